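# IUPAC monoisotopic masses (most abundant isotope), Da. Precision >= 6
# decimals is required to reproduce 3-decimal printed m/z values.
.monoisotopic_table <- c(
  H  = 1.0078250319,
  C  = 12,
  N  = 14.0030740052,
  O  = 15.9949146221,
  F  = 18.9984032,
  Na = 22.98976928,
  Mg = 23.985041697,
  Si = 27.9769265327,
  P  = 30.97376151,
  S  = 31.97207069,
  Cl = 34.96885271,
  K  = 38.9637069,
  Ca = 39.96259098,
  Br = 78.9183376,
  I  = 126.904468
)

#' Physical constants used in ion-species mass bookkeeping (Da)
#'
#' Proton and electron rest masses. PTR ionization transfers whole protons,
#' electrons or hydroxide ions between the reagent and the analyte, so the
#' m/z of a singly charged ion differs from the neutral monoisotopic mass by
#' combinations of these constants rather than by a plain hydrogen atom.
#'
#' @format Named numeric scalars.
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
proton_mass <- 1.0072765

#' @rdname mass-constants
#' @export
electron_mass <- 0.0005486

# hydroxide anion: O + H + e
hydroxide_mass <- 15.9949146221 + 1.0078250319 + 0.0005486

#' Parse a molecular formula in Hill notation
#'
#' Accepts element symbols with optional counts and nested parenthesised
#' groups, e.g. `"C18H34O2"` or `"C3(CH2)2O"`. Charge tokens are not
#' accepted: compositions describe neutral molecules.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts (elements in first-seen
#'   order, repeated symbols summed).
#' @examples
#' parse_formula("C18H34O2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  chars <- strsplit(formula, "")[[1]]
  pos <- 1L

  read_count <- function() {
    start <- pos
    while (pos <= length(chars) && grepl("[0-9]", chars[pos])) pos <<- pos + 1L
    if (pos == start) 1L else as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }

  parse_group <- function() {
    counts <- integer(0)
    add <- function(el, n) {
      counts[el] <<- if (el %in% names(counts)) counts[[el]] + n else n
    }
    while (pos <= length(chars)) {
      ch <- chars[pos]
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- parse_group()
        if (pos > length(chars) || chars[pos] != ")")
          stop("unbalanced parenthesis in formula '", formula, "'")
        pos <<- pos + 1L
        mult <- read_count()
        for (el in names(inner)) add(el, inner[[el]] * mult)
      } else if (ch == ")") {
        break
      } else if (grepl("[A-Z]", ch)) {
        el <- ch
        pos <<- pos + 1L
        if (pos <= length(chars) && grepl("[a-z]", chars[pos])) {
          el <- paste0(el, chars[pos])
          pos <<- pos + 1L
        }
        add(el, read_count())
      } else {
        stop("unexpected character '", ch, "' in formula '", formula, "'")
      }
    }
    counts
  }

  out <- parse_group()
  if (pos <= length(chars))
    stop("unbalanced parenthesis in formula '", formula, "'")
  out
}

#' Format a composition as a Hill-notation formula string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically
#' (the convention used by structure databases).
#'
#' @param composition Named integer vector of element counts.
#' @return Formula string.
#' @export
format_formula <- function(composition) {
  composition <- composition[composition > 0]
  els <- names(composition)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(composition[ord] == 1L, "", composition[ord]), collapse = "")
}

#' Monoisotopic mass of a neutral composition
#'
#' Sum of element count times the monoisotopic (most abundant isotope)
#' atomic mass.
#'
#' @param composition Either a formula string (see [parse_formula()]) or a
#'   named numeric vector of element counts. An empty composition has mass 0.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C18H34O2") # oleic acid, 282.256
#' @export
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (length(composition) == 0L) return(0)
  unknown <- setdiff(names(composition), names(.monoisotopic_table))
  if (length(unknown))
    stop("no monoisotopic mass for element(s): ", paste(unknown, collapse = ", "))
  sum(.monoisotopic_table[names(composition)] * composition)
}

#' PTR ion-species rules
#'
#' The six ion species produced by water chemical ionization, with exact
#' mass deltas relative to the neutral molecule including electron-mass
#' bookkeeping: protonation `[M+H]+` (+proton), electron loss `[M]+`
#' (-electron), hydroxide abstraction `[M-OH]+` (-hydroxide), and the
#' negative-mode mirrors `[M-H]-`, `[M]-`, `[M+OH]-`. Ammonium adduction
#' `[M+NH4]+` is available but disabled by default: it is seen for a few
#' authentic standards, not in cell screening.
#'
#' @param polarity `"positive"`, `"negative"`, or `"both"`.
#' @param include_ammonium Include the `[M+NH4]+` rule (default `FALSE`).
#' @return Data frame with columns `label`, `delta_mass` (Da), `polarity`.
#' @export
ion_species_rules <- function(polarity = c("both", "positive", "negative"),
                              include_ammonium = FALSE) {
  polarity <- match.arg(polarity)
  ammonium <- 14.0030740052 + 4 * 1.0078250319 - electron_mass
  rules <- data.frame(
    label = c("[M+H]+", "[M]+", "[M-OH]+", "[M-H]-", "[M]-", "[M+OH]-", "[M+NH4]+"),
    delta_mass = c(proton_mass, -electron_mass, -hydroxide_mass,
                   -proton_mass, electron_mass, hydroxide_mass, ammonium),
    polarity = c("positive", "positive", "positive",
                 "negative", "negative", "negative", "positive"),
    stringsAsFactors = FALSE
  )
  if (!include_ammonium) rules <- rules[rules$label != "[M+NH4]+", ]
  if (polarity != "both") rules <- rules[rules$polarity == polarity, ]
  rownames(rules) <- NULL
  rules
}

#' Theoretical m/z of an ion species
#'
#' Monoisotopic mass of the neutral composition plus the species mass delta;
#' all species are singly charged, so m/z equals the ion mass.
#'
#' @param composition Formula string or named count vector (neutral molecule).
#' @param species Species label (e.g. `"[M+H]+"`, `"[M-H]-"`) or a one-row
#'   rule data frame as returned by [ion_species_rules()].
#' @return m/z in Da.
#' @examples
#' theoretical_mz("C20H32O2", "[M-H]-") # 303.233
#' @export
theoretical_mz <- function(composition, species) {
  if (is.character(species)) {
    rules <- ion_species_rules("both", include_ammonium = TRUE)
    row <- rules[rules$label == species, ]
    if (nrow(row) != 1L)
      stop("unknown ion species '", species, "'")
  } else {
    row <- species
  }
  mz <- monoisotopic_mass(composition) + row$delta_mass
  if (mz <= 0) stop("non-positive m/z for composition")
  mz
}
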