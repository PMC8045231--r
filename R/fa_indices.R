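#' Parse fatty-acid labels
#'
#' Parses the gas-chromatography shorthand `C<carbons>:<double bonds>` with an
#' omega-class suffix (`n3`, `n6`, `n7` or `n9`) required for unsaturated
#' acids, e.g. `"C16:0"`, `"C18:1n9"`, `"C22:6n3"`. The saturation class is
#' derived from the number of double bonds: 0 = SFA, 1 = MUFA, >= 2 = PUFA.
#'
#' @param labels Character vector of fatty-acid labels.
#' @return A data frame with one row per label and columns `label`,
#'   `chain_length`, `n_double_bonds`, `omega_class` (one of `"n3"`, `"n6"`,
#'   `"n7"`, `"n9"`, `"none"`) and `sat_class` (`"SFA"`, `"MUFA"`, `"PUFA"`).
#' @examples
#' parse_fa_label(c("C16:0", "C18:1n9", "C22:6n3"))
#' @export
parse_fa_label <- function(labels) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  m <- regmatches(labels, regexec("^C([0-9]+):([0-9]+)(n([0-9]+))?$", labels))
  bad <- labels[vapply(m, length, 1L) == 0L]
  if (length(bad))
    stop("malformed fatty-acid label(s): ", paste(sQuote(bad), collapse = ", "),
         "; expected C<carbons>:<bonds>[n<omega>]")
  chain <- vapply(m, function(x) as.integer(x[2L]), 1L)
  bonds <- vapply(m, function(x) as.integer(x[3L]), 1L)
  omega <- vapply(m, function(x) x[5L], "")
  if (any(chain < 4L))
    stop("chain length below 4 carbons in label(s): ",
         paste(sQuote(labels[chain < 4L]), collapse = ", "))
  sat <- ifelse(bonds == 0L, "SFA", ifelse(bonds == 1L, "MUFA", "PUFA"))
  # saturated acids carry no omega class; unsaturated ones must name theirs
  if (any(bonds == 0L & omega != ""))
    stop("saturated label(s) carry an omega suffix: ",
         paste(sQuote(labels[bonds == 0L & omega != ""]), collapse = ", "))
  if (any(bonds > 0L & omega == ""))
    stop("unsaturated label(s) lack an omega suffix: ",
         paste(sQuote(labels[bonds > 0L & omega == ""]), collapse = ", "))
  ocl <- ifelse(omega == "", "none", paste0("n", omega))
  if (!all(ocl %in% c("none", "n3", "n6", "n7", "n9")))
    stop("unsupported omega class in label(s): ",
         paste(sQuote(labels[!ocl %in% c("none", "n3", "n6", "n7", "n9")]),
               collapse = ", "))
  data.frame(label = labels, chain_length = chain, n_double_bonds = bonds,
             omega_class = ocl, sat_class = sat, stringsAsFactors = FALSE)
}

#' Construct a validated species x fatty-acid composition table
#'
#' Rows are species, columns are fatty acids in mol% (molar percentage).
#' Each row must sum to 100 within `closure_tol`; with `renormalize = TRUE`
#' rows are rescaled to sum to exactly 100 after validation.
#'
#' @param proportions Numeric matrix (or data frame) of mol% values with
#'   species as row names and fatty-acid labels as column names.
#' @param closure_tol Allowed deviation of each row sum from 100 (mol%).
#' @param renormalize Rescale rows to exactly 100 after validation.
#' @return An object of class `composition_table`: a list with elements
#'   `species`, `fa` (parsed descriptors, see [parse_fa_label()]) and
#'   `proportions` (numeric matrix, mol%).
#' @export
composition_table <- function(proportions, closure_tol = 0.5,
                              renormalize = FALSE) {
  if (is.data.frame(proportions)) proportions <- as.matrix(proportions)
  stopifnot(is.matrix(proportions), is.numeric(proportions))
  if (is.null(rownames(proportions)))
    stop("species identifiers are required as row names")
  if (is.null(colnames(proportions)))
    stop("fatty-acid labels are required as column names")
  species <- rownames(proportions)
  if (anyDuplicated(species))
    stop("duplicated species identifiers: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  fa <- parse_fa_label(colnames(proportions))
  if (any(!is.finite(proportions)) || any(proportions < 0))
    stop("proportions must be finite and non-negative")
  rs <- rowSums(proportions)
  off <- abs(rs - 100) > closure_tol
  if (any(off))
    stop("row sums deviate from 100 by more than ", closure_tol,
         " mol% for: ", paste(species[off], collapse = ", "))
  if (renormalize) proportions <- proportions / rs * 100
  structure(list(species = species, fa = fa, proportions = proportions),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("composition_table:", length(x$species), "species x",
      nrow(x$fa), "fatty acids (mol%)\n")
  cat("fatty acids:", paste(x$fa$label, collapse = " "), "\n")
  invisible(x)
}

#' Saturation-class sums and the n-3/total-PUFA ratio
#'
#' Sums mol% within saturation classes and computes the proportion of n-3
#' PUFA among total PUFA (a fraction in \[0, 1\]). Species whose total PUFA
#' is zero get `NA` for the ratio, with a warning.
#'
#' @param comp A [composition_table()].
#' @return Data frame with columns `species`, `sfa`, `mufa`, `pufa` (mol%)
#'   and `n3_over_total_pufa` (fraction).
#' @export
class_sums <- function(comp) {
  stopifnot(inherits(comp, "composition_table"))
  p <- comp$proportions
  cls <- comp$fa$sat_class
  sfa <- rowSums(p[, cls == "SFA", drop = FALSE])
  mufa <- rowSums(p[, cls == "MUFA", drop = FALSE])
  pufa <- rowSums(p[, cls == "PUFA", drop = FALSE])
  n3 <- rowSums(p[, cls == "PUFA" & comp$fa$omega_class == "n3", drop = FALSE])
  ratio <- ifelse(pufa > 0, n3 / pufa, NA_real_)
  if (anyNA(ratio))
    warning("total PUFA is zero for ", sum(is.na(ratio)),
            " species; n-3/total-PUFA ratio set to NA")
  data.frame(species = comp$species, sfa = sfa, mufa = mufa, pufa = pufa,
             n3_over_total_pufa = ratio, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Average chain length (ACL)
#'
#' Proportion-weighted mean carbon-chain length,
#' `sum(mol fraction * chain length)` per species.
#'
#' @param comp A [composition_table()].
#' @return Named numeric vector (carbons), one value per species.
#' @export
average_chain_length <- function(comp) {
  stopifnot(inherits(comp, "composition_table"))
  out <- drop((comp$proportions / 100) %*% comp$fa$chain_length)
  names(out) <- comp$species
  out
}

#' Double bond index (DBI)
#'
#' Mean number of double bonds per 100 fatty acids:
#' `sum(mol% * double bonds)` per species.
#'
#' @param comp A [composition_table()].
#' @return Named numeric vector, one value per species.
#' @export
double_bond_index <- function(comp) {
  stopifnot(inherits(comp, "composition_table"))
  out <- drop(comp$proportions %*% comp$fa$n_double_bonds)
  names(out) <- comp$species
  out
}

# peroxidation-susceptibility weights, keyed by number of double bonds 1..6
.pi_coef <- c(0.025, 1, 2, 4, 6, 8)

#' Peroxidizability index (PI)
#'
#' Weighted unsaturation sum reflecting susceptibility to peroxidative
#' damage: `0.025 * mol% monoenoic + 1 * dienoic + 2 * trienoic +
#' 4 * tetraenoic + 6 * pentaenoic + 8 * hexaenoic`. Fatty acids with more
#' than six double bonds have no defined coefficient and raise an error.
#'
#' @param comp A [composition_table()].
#' @return Named numeric vector, one value per species.
#' @export
peroxidizability_index <- function(comp) {
  stopifnot(inherits(comp, "composition_table"))
  b <- comp$fa$n_double_bonds
  if (any(b > 6L))
    stop("no peroxidizability coefficient for fatty acids with > 6 double ",
         "bonds: ", paste(comp$fa$label[b > 6L], collapse = ", "))
  w <- ifelse(b == 0L, 0, .pi_coef[pmax(b, 1L)])
  out <- drop(comp$proportions %*% w)
  names(out) <- comp$species
  out
}

# explicit enumeration: only these acids enter the AI numerator
.ai_numerator <- c("C20:3n6", "C20:5n3", "C22:6n3")
.ai_denominator <- "C20:4n6"

#' Anti-inflammatory index (AI)
#'
#' Percentage ratio of the anti-inflammatory fatty acids 20:3n-6, 20:5n-3
#' and 22:6n-3 to pro-inflammatory arachidonic acid 20:4n-6:
#' `100 * (mol% 20:3n6 + 20:5n3 + 22:6n3) / mol% 20:4n6`. Numerator acids
#' absent from the table contribute zero; arachidonic acid must be a column,
#' and species with zero arachidonic acid get `NA` with a warning.
#'
#' @param comp A [composition_table()].
#' @return Named numeric vector, one value per species.
#' @export
anti_inflammatory_index <- function(comp) {
  stopifnot(inherits(comp, "composition_table"))
  labs <- comp$fa$label
  if (!.ai_denominator %in% labs)
    stop("anti-inflammatory index requires arachidonic acid (",
         .ai_denominator, ") in the table")
  num_cols <- intersect(.ai_numerator, labs)
  num <- if (length(num_cols))
    rowSums(comp$proportions[, num_cols, drop = FALSE]) else
    rep(0, length(comp$species))
  den <- comp$proportions[, .ai_denominator]
  out <- ifelse(den > 0, 100 * num / den, NA_real_)
  if (anyNA(out))
    warning("arachidonic acid is zero for ", sum(is.na(out)),
            " species; anti-inflammatory index set to NA")
  names(out) <- comp$species
  out
}

#' All fatty-acid composition indices for a table
#'
#' Convenience wrapper computing, per species: class sums (SFA, MUFA, PUFA),
#' the n-3/total-PUFA ratio, average chain length, double bond index,
#' peroxidizability index and anti-inflammatory index.
#'
#' @param comp A [composition_table()].
#' @return Data frame with columns `species`, `sfa`, `mufa`, `pufa`,
#'   `n3_over_total_pufa`, `acl`, `dbi`, `pi_index`, `ai`.
#' @export
fa_index_table <- function(comp) {
  out <- class_sums(comp)
  out$acl <- unname(average_chain_length(comp))
  out$dbi <- unname(double_bond_index(comp))
  out$pi_index <- unname(peroxidizability_index(comp))
  out$ai <- unname(anti_inflammatory_index(comp))
  out
}

#' Read a composition table from CSV/TSV
#'
#' Expects the first column to hold species identifiers and the remaining
#' column names to be fatty-acid labels in the `C<x>:<y>n<z>` dialect.
#'
#' @param path File path.
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @inheritParams composition_table
#' @return A [composition_table()].
#' @export
read_composition_csv <- function(path, sep = ",", closure_tol = 0.5,
                                 renormalize = FALSE) {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- as.character(d[[1L]])
  composition_table(m, closure_tol = closure_tol, renormalize = renormalize)
}

#' Write an index table (or any data frame) as CSV
#'
#' @param x Data frame, e.g. the output of [fa_index_table()].
#' @param path Output file path.
#' @export
write_index_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
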