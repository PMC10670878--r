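#' Assign a protein's compartment from its regulons
#'
#' Deterministic rule with vegetative precedence: membership of SigA, SigH
#' or Spo0A marks a protein vegetative regardless of other regulons; sigF or
#' sigG membership marks it forespore-specific; sigE or sigK mother-cell
#' specific; membership of both cell types (without vegetative membership)
#' is ambiguous; none of the above is unknown.
#'
#' @param protein_id Character vector of protein IDs.
#' @param regulon_map Data frame with `protein_id` and comma-separated
#'   `regulons` (see [read_regulon_map()]).
#' @return Character vector in `{mother_cell, forespore, vegetative,
#'   ambiguous, unknown}` with the contributing regulons as the
#'   `"regulons"` attribute.
#' @export
assign_compartment <- function(protein_id, regulon_map) {
  idx <- match(protein_id, regulon_map$protein_id)
  regs <- ifelse(is.na(idx), "", regulon_map$regulons[idx])
  veg_set <- c("SigA", "SigH", "Spo0A")
  fs_set <- c("SigF", "SigG")
  mc_set <- c("SigE", "SigK")
  out <- vapply(regs, function(r) {
    rs <- trimws(strsplit(r, ",")[[1]])
    if (length(rs) == 0) return("unknown")
    if (any(rs %in% veg_set)) return("vegetative")
    is_fs <- any(rs %in% fs_set)
    is_mc <- any(rs %in% mc_set)
    if (is_fs && is_mc) return("ambiguous")
    if (is_fs) return("forespore")
    if (is_mc) return("mother_cell")
    "unknown"
  }, character(1), USE.NAMES = FALSE)
  attr(out, "regulons") <- regs
  out
}

#' Filter sporulation-specific arginine-containing peptides
#'
#' Retains peptides with at least one arginine whose protein maps to a
#' sporulation-specific compartment (mother cell or forespore). Peptides
#' without arginine, and vegetative / ambiguous / unknown proteins, are
#' excluded from the headline fractions but tallied in the attached filter
#' report; the report's categories partition the input exactly.
#'
#' @param peptides Data frame with `protein_id`, `arg_count`, `heavy` (see
#'   [read_peptide_table()]).
#' @param regulon_map Regulon map data frame.
#' @return The retained peptides with added `compartment` and `regulons`
#'   columns; attribute `filter_report` (named counts: `no_arginine`,
#'   `mother_cell`, `forespore`, `vegetative`, `ambiguous`, `unknown`).
#' @export
filter_peptides <- function(peptides, regulon_map) {
  comp <- assign_compartment(peptides$protein_id, regulon_map)
  regs <- attr(comp, "regulons")
  category <- ifelse(peptides$arg_count < 1, "no_arginine", comp)
  report <- vapply(c("no_arginine", "mother_cell", "forespore",
                     "vegetative", "ambiguous", "unknown"),
                   function(k) sum(category == k), integer(1))
  if (any(comp == "unknown")) {
    message(sprintf("%d peptide(s) from unmapped protein(s) excluded",
                    sum(comp == "unknown")))
  }
  keep <- category %in% c("mother_cell", "forespore")
  out <- peptides[keep, , drop = FALSE]
  out$compartment <- comp[keep]
  out$regulons <- regs[keep]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}

wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  # only the confidence interval (the Wilson score interval) is used; the
  # chi-squared continuity warning concerns the test statistic, not the CI
  ci <- suppressWarnings(stats::prop.test(x, n, correct = FALSE,
                                          conf.level = conf)$conf.int)
  as.numeric(ci)
}

#' Heavy-arginine incorporation summary
#'
#' Per-compartment (and, for forespore peptides, per-regulon sigF/sigG)
#' counts and heavy fractions with 95% Wilson score confidence intervals.
#'
#' @param peptides Filtered peptides from [filter_peptides()] (must carry
#'   `compartment`, `regulons`, `heavy`).
#' @return Data frame of class `incorporation_summary` with `group`,
#'   `level` (`"compartment"` or `"regulon"`), `n_peptides`, `n_heavy`,
#'   `fraction`, `ci_low`, `ci_high`.
#' @export
incorporation_summary <- function(peptides) {
  if (nrow(peptides) == 0) stop_param("no peptides to summarize")
  if (!all(c("compartment", "heavy") %in% names(peptides))) {
    stop_param("peptides must come from filter_peptides()")
  }
  one <- function(sel, group, level) {
    n <- sum(sel)
    if (n == 0) {
      warning(sprintf("no peptides in %s '%s'; omitted", level, group))
      return(NULL)
    }
    x <- sum(peptides$heavy[sel])
    ci <- wilson_interval(x, n)
    data.frame(group = group, level = level, n_peptides = n, n_heavy = x,
               fraction = x / n, ci_low = ci[1], ci_high = ci[2])
  }
  rows <- list(
    one(peptides$compartment == "mother_cell", "mother_cell", "compartment"),
    one(peptides$compartment == "forespore", "forespore", "compartment"),
    one(peptides$compartment == "forespore" &
          grepl("\\bSigF\\b", peptides$regulons), "SigF", "regulon"),
    one(peptides$compartment == "forespore" &
          grepl("\\bSigG\\b", peptides$regulons) &
          !grepl("\\bSigF\\b", peptides$regulons), "SigG", "regulon")
  )
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("incorporation_summary", "data.frame")
  out
}

#' Fold-change of incorporation over a control summary
#'
#' `fold = fraction / control_fraction` per matching group, with a
#' conservative interval from the ratio of Wilson bounds. A zero control
#' fraction leaves the fold undefined (flagged, not `NaN`).
#'
#' @param summary,control_summary `incorporation_summary` objects.
#' @return Data frame with `group`, `level`, `fraction`,
#'   `control_fraction`, `fold`, `fold_low`, `fold_high`, `fold_defined`.
#' @export
fold_change <- function(summary, control_summary) {
  common <- intersect(summary$group, control_summary$group)
  if (length(common) == 0) stop_param("no matching groups between summaries")
  out <- lapply(common, function(g) {
    a <- summary[summary$group == g, ][1, ]
    b <- control_summary[control_summary$group == g, ][1, ]
    defined <- b$fraction > 0
    data.frame(
      group = g, level = a$level,
      fraction = a$fraction, control_fraction = b$fraction,
      fold = if (defined) a$fraction / b$fraction else NA_real_,
      fold_low = if (defined && b$ci_high > 0) a$ci_low / b$ci_high else NA_real_,
      fold_high = if (defined && b$ci_low > 0) a$ci_high / b$ci_low else NA_real_,
      fold_defined = defined
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full SILAC summarization from files
#'
#' Reads a peptide table and regulon map, filters sporulation-specific
#' arginine peptides, and returns the incorporation summary (plus folds
#' when a control peptide table is supplied).
#'
#' @param peptide_path Peptide CSV/TSV path.
#' @param regulon_path Regulon map TSV path.
#' @param control_path Optional control peptide table path.
#' @param aliases Column aliases for [read_peptide_table()].
#' @return List with `summary`, `filter_report`, and `folds` (when a
#'   control is given).
#' @export
silac_summarize <- function(peptide_path, regulon_path, control_path = NULL,
                            aliases = c(peptide = "peptide_id",
                                        protein = "protein_id",
                                        arg_count = "arg_count",
                                        heavy = "heavy")) {
  regmap <- read_regulon_map(regulon_path)
  pep <- filter_peptides(read_peptide_table(peptide_path, aliases), regmap)
  summ <- incorporation_summary(pep)
  out <- list(summary = summ, filter_report = attr(pep, "filter_report"))
  if (!is.null(control_path)) {
    ctl <- filter_peptides(read_peptide_table(control_path, aliases), regmap)
    out$folds <- fold_change(summ, incorporation_summary(ctl))
  }
  out
}
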