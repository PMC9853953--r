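# Formula-level annotation against an SDF structure database.
#
# The database is normalised before use: each record is desalted (only the
# largest covalent fragment is kept), isotope labels are replaced by the
# most abundant isotope, the molecular formula is computed from the atom
# and bond blocks with MDL-style implicit hydrogens, and identical
# formulas are pooled with a count of contributing structures (isomers are
# not resolvable at formula level). Candidates are the cross product of
# pooled formulas with the PTR ion-species rules for the run polarity.

# default MDL valences used to fill implicit hydrogens; for multi-valence
# elements the smallest valence >= the bond-order sum applies
.default_valences <- list(
  H = 1, D = 1, T = 1, C = 4, N = c(3, 5), O = 2, F = 1, Na = 1,
  Mg = 2, Si = 4, P = c(3, 5), S = c(2, 4, 6), Cl = 1, K = 1, Ca = 2,
  Br = 1, I = c(1, 3, 5, 7))

# composition of the largest connected fragment of one ChemmineR SDF
# object, isotopes substituted; NULL when the record cannot be interpreted
.fragment_composition <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) return(NULL)
  symbols <- sub("_\\d+$", "", rownames(ab))
  n_atoms <- length(symbols)
  bb <- ChemmineR::bondblock(sdf)
  edges <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(numeric(0), ncol = 3)
  } else {
    cbind(bb[, 1], bb[, 2], bb[, 3])
  }
  # connected components by label propagation (union-find is overkill here)
  comp <- seq_len(n_atoms)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  keep_comp <- as.integer(names(sizes)[which.max(sizes)])  # tie -> first
  keep <- comp == keep_comp
  # bond-order sum per kept atom (aromatic/query bond orders unsupported)
  bsum <- numeric(n_atoms)
  for (e in seq_len(nrow(edges))) {
    o <- edges[e, 3]
    if (o > 3) return(NULL)
    bsum[edges[e, 1]] <- bsum[edges[e, 1]] + o
    bsum[edges[e, 2]] <- bsum[edges[e, 2]] + o
  }
  counts <- integer(0)
  add <- function(el, n) {
    counts[el] <<- if (el %in% names(counts)) counts[[el]] + n else as.integer(n)
  }
  for (i in which(keep)) {
    el <- symbols[i]
    val <- .default_valences[[el]]
    if (is.null(val)) return(NULL)
    # isotope substitution: D/T count as H
    add(if (el %in% c("D", "T")) "H" else el, 1L)
    fit <- val[val >= bsum[i]]
    implicit <- if (length(fit)) min(fit) - bsum[i] else 0
    if (implicit > 0) add("H", implicit)
  }
  counts
}

#' Normalise an SDF structure database to pooled formulas
#'
#' Per record: keep only the largest connected fragment (desalting),
#' substitute isotope-labelled atoms (D, T) with the most abundant isotope,
#' compute the molecular formula with implicit hydrogens filled by standard
#' valences, and drop structures above `max_mass`. Identical formulas are
#' pooled, counting the distinct contributing structures. Records that
#' cannot be interpreted (unknown elements, aromatic/query bonds) are
#' skipped with a warning reporting the count.
#'
#' @param sdf Path to an SDF (V2000) file, a character vector of SDF text,
#'   or a `ChemmineR::SDFset`.
#' @param max_mass Drop formulas with monoisotopic mass above this (default
#'   1200 Da, the screening mass range).
#' @return Data frame of formula records: `formula`, `monoisotopic_mass`,
#'   `n_structures`, sorted by mass. Attribute `n_skipped` reports skipped
#'   records.
#' @export
normalize_structures <- function(sdf, max_mass = 1200) {
  if (inherits(sdf, "SDFset")) {
    set <- sdf
    n_total <- length(ChemmineR::cid(set))
  } else {
    path <- if (length(sdf) == 1L && file.exists(sdf)) {
      sdf
    } else {
      tmp <- tempfile(fileext = ".sdf")
      on.exit(unlink(tmp))
      writeLines(sdf, tmp)
      tmp
    }
    # records the reader rejects outright count as skipped too
    n_total <- length(ChemmineR::sdfstr2list(ChemmineR::read.SDFstr(path)))
    set <- suppressWarnings(ChemmineR::read.SDFset(path))
  }
  formulas <- character(0)
  masses <- numeric(0)
  n_skipped <- n_total - length(ChemmineR::cid(set))
  for (i in seq_along(ChemmineR::cid(set))) {
    comp <- tryCatch(.fragment_composition(set[[i]]), error = function(e) NULL)
    m <- if (is.null(comp)) NULL else
      tryCatch(monoisotopic_mass(comp), error = function(e) NULL)
    if (is.null(m)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (m > max_mass) next
    formulas <- c(formulas, format_formula(comp))
    masses <- c(masses, m)
  }
  if (n_skipped > 0L)
    warning(n_skipped, " SDF record(s) skipped (uninterpretable)")
  if (length(formulas) == 0L) {
    out <- data.frame(formula = character(0), monoisotopic_mass = numeric(0),
                      n_structures = integer(0), stringsAsFactors = FALSE)
  } else {
    tab <- table(formulas)
    out <- data.frame(formula = names(tab),
                      monoisotopic_mass = masses[match(names(tab), formulas)],
                      n_structures = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(out$monoisotopic_mass), ]
    rownames(out) <- NULL
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Enumerate candidate ions from pooled formulas
#'
#' Cross product of every formula record with every ion-species rule for
#' the requested polarity.
#'
#' @param formulas Formula records from [normalize_structures()].
#' @param polarity `"positive"` or `"negative"`.
#' @param include_ammonium Include `[M+NH4]+` (default `FALSE`).
#' @return Data frame: `formula`, `species`, `theoretical_mz`,
#'   `n_structures`, sorted by `theoretical_mz`.
#' @export
build_candidates <- function(formulas, polarity = c("positive", "negative"),
                             include_ammonium = FALSE) {
  polarity <- match.arg(polarity)
  rules <- ion_species_rules(polarity, include_ammonium = include_ammonium)
  out <- do.call(rbind, lapply(seq_len(nrow(rules)), function(j) {
    data.frame(formula = formulas$formula,
               species = rules$label[j],
               theoretical_mz = formulas$monoisotopic_mass + rules$delta_mass[j],
               n_structures = formulas$n_structures,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$theoretical_mz > 0, ]
  out <- out[order(out$theoretical_mz), ]
  rownames(out) <- NULL
  out
}

#' Match observed ions to candidate species within a mass tolerance
#'
#' For each observed ion, every candidate whose theoretical m/z lies within
#' the tolerance of the observed mean m/z is reported, sorted by |delta m|.
#' The replicate standard deviation is carried through for reporting; with
#' `gate = "replicate_sd"` the per-ion tolerance becomes that SD instead of
#' the fixed window.
#'
#' @param observed Data frame with columns `mz_mean` (Da) and optionally
#'   `sd_mda` (replicate SD, mDa) and `n` (replicates).
#' @param candidates Candidate table from [build_candidates()].
#' @param tolerance_mda Fixed match half-window in mDa (default 3).
#' @param gate `"fixed"` (default) gates on `tolerance_mda`;
#'   `"replicate_sd"` gates on each ion's own `sd_mda`.
#' @return Data frame of annotation matches: `observed_mz`, `sd_mda`, `n`,
#'   `formula`, `species`, `theoretical_mz`, `delta_mda`, `isomer_extra`
#'   (structures sharing the formula beyond the first).
#' @export
match_ions <- function(observed, candidates, tolerance_mda = 3,
                       gate = c("fixed", "replicate_sd")) {
  gate <- match.arg(gate)
  observed <- as.data.frame(observed)
  if (!"sd_mda" %in% names(observed)) observed$sd_mda <- NA_real_
  if (!"n" %in% names(observed)) observed$n <- NA_integer_
  res <- list()
  for (i in seq_len(nrow(observed))) {
    tol <- if (gate == "replicate_sd") observed$sd_mda[i] else tolerance_mda
    d <- (observed$mz_mean[i] - candidates$theoretical_mz) * 1000
    hit <- which(abs(d) <= tol)
    if (length(hit) == 0L) next
    hit <- hit[order(abs(d[hit]))]
    res[[length(res) + 1L]] <- data.frame(
      observed_mz = observed$mz_mean[i],
      sd_mda = observed$sd_mda[i],
      n = observed$n[i],
      formula = candidates$formula[hit],
      species = candidates$species[hit],
      theoretical_mz = candidates$theoretical_mz[hit],
      delta_mda = d[hit],
      isomer_extra = candidates$n_structures[hit] - 1L,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(observed_mz = numeric(0), sd_mda = numeric(0),
                      n = integer(0), formula = character(0),
                      species = character(0), theoretical_mz = numeric(0),
                      delta_mda = numeric(0), isomer_extra = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
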