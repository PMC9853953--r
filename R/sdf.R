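# Synthetic structure-database fixture in SDF V2000, standing in for a
# lipid structure database download. Records are linear fatty acids built
# programmatically (Kekule structures, heavy atoms only, implicit
# hydrogens), plus deliberately awkward variants: a sodium salt written as
# a disconnected counter-ion fragment, a deuterium-labelled acid, and
# positional isomers sharing one formula -- so every normalisation branch
# (desalting, isotope substitution, formula pooling, mass cutoff) is
# exercised by a few dozen records.

# one fatty-acid SDF record: n_carbon chain, C=C bonds after the listed
# carbons (counted from the carboxyl carbon), optional disconnected Na
# fragment, optional 3 explicit deuteriums on the terminal carbon
.fatty_acid_record <- function(title, n_carbon, double_after = integer(0),
                               sodium = FALSE, deuterate = FALSE) {
  stopifnot(n_carbon >= 2L, all(double_after >= 2L & double_after < n_carbon))
  symbols <- c(rep("C", n_carbon), "O", "O")
  bonds <- rbind(
    c(1L, n_carbon + 1L, 2L),                       # C1=O
    c(1L, n_carbon + 2L, 1L))                       # C1-OH
  for (i in seq_len(n_carbon - 1L))
    bonds <- rbind(bonds, c(i, i + 1L, if (i %in% double_after) 2L else 1L))
  if (deuterate) {
    for (k in 1:3) {
      symbols <- c(symbols, "D")
      bonds <- rbind(bonds, c(n_carbon, length(symbols), 1L))
    }
  }
  if (sodium) symbols <- c(symbols, "Na")           # disconnected fragment
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, symbols)
  bond_lines <- sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2], bonds[, 3])
  c(title, "  sfeptr", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(symbols), nrow(bonds)),
    atom_lines, bond_lines, "M  END", "$$$$")
}

#' Generate a synthetic SDF structure fixture
#'
#' Deterministically builds `n_structures` fatty-acid records. The first
#' five are fixed so the normalisation corner cases are always present:
#' oleic acid (C18H34O2), its sodium salt as a two-fragment record, a
#' d3-labelled oleic acid, and two positional isomers of C20H32O2
#' (arachidonic-type). Further records are filler acids with seeded random
#' chain lengths and unsaturation; every sixth filler is an over-long
#' chain whose mass exceeds the 1200 Da screening cutoff.
#'
#' @param n_structures Number of records (>= 1).
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param path Optional file path; when given the SDF text is written there.
#' @return Character vector of SDF lines (invisibly when `path` is given).
#' @export
make_structure_fixture <- function(n_structures, seed = 1L, path = NULL) {
  stopifnot(n_structures >= 1L)
  fixed <- list(
    function() .fatty_acid_record("oleic acid", 18L, 9L),
    function() .fatty_acid_record("sodium oleate (salt)", 18L, 9L, sodium = TRUE),
    function() .fatty_acid_record("oleic acid-d3", 18L, 9L, deuterate = TRUE),
    function() .fatty_acid_record("arachidonic acid", 20L, c(5L, 8L, 11L, 14L)),
    function() .fatty_acid_record("eicosatetraenoic acid (8,11,14,17)", 20L,
                                  c(8L, 11L, 14L, 17L)))
  set.seed(seed)
  records <- character(0)
  for (i in seq_len(n_structures)) {
    rec <- if (i <= length(fixed)) {
      fixed[[i]]()
    } else if ((i - length(fixed)) %% 6L == 0L) {
      .fatty_acid_record(sprintf("filler acid %d (overlong)", i), 90L)
    } else {
      nc <- sample(10:26, 1L)
      ndb <- sample(0:min(4L, nc - 2L), 1L)
      dpos <- if (ndb > 0) sort(sample(2:(nc - 1L), ndb)) else integer(0)
      .fatty_acid_record(sprintf("filler acid %d (C%d:%d)", i, nc, ndb),
                         nc, dpos)
    }
    records <- c(records, rec)
  }
  if (!is.null(path)) {
    writeLines(records, path)
    return(invisible(records))
  }
  records
}
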