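#' Parameters for the synthetic SILAC peptide-table generator
#'
#' Emulates a peptide-level MS search export from a cell-specific SILAC
#' experiment: a surrogate proteome structured by regulon class (sigF/sigG
#' forespore, sigE/sigK mother cell, SigA/SigH/Spo0A vegetative), tryptic
#' peptides with Poisson-distributed arginine counts, and per-compartment
#' probabilities that a peptide carries at least one heavy
#' (13C6,15N4) arginine. The `scenario` presets encode the three strain
#' configurations: `control` (no transporter; both compartments at the
#' nonspecific background incorporation), `mc_transporter` (arginine
#' importer expressed in the mother cell: strong labeling of mother-cell
#' peptides and, via intercellular transport, of forespore peptides), and
#' `fs_transporter` (importer in the forespore: a modest rise in forespore
#' labeling). Any preset probability can be overridden through `p_heavy`.
#'
#' @param n_proteins Named counts of proteins per regulon class; names among
#'   `sigF`, `sigG`, `sigE`, `sigK`, `vegetative`.
#' @param peptides_per_protein Distribution spec: a single number (fixed) or
#'   `list(dist = "poisson", lambda =, min =)`.
#' @param arg_per_peptide Distribution spec for arginine counts (minimum 0).
#' @param scenario One of `"control"`, `"mc_transporter"`,
#'   `"fs_transporter"`.
#' @param p_heavy Optional named list overriding the scenario probabilities
#'   for `mother_cell`, `forespore`, `background`.
#' @param seed Integer seed.
#' @return Object of class `peptide_table_params`.
#' @export
peptide_table_params <- function(n_proteins = c(sigF = 80, sigG = 80,
                                                sigE = 120, sigK = 120,
                                                vegetative = 120),
                                 peptides_per_protein = list(dist = "poisson",
                                                             lambda = 10, min = 1),
                                 arg_per_peptide = list(dist = "poisson",
                                                        lambda = 1.5, min = 0),
                                 scenario = c("control", "mc_transporter",
                                              "fs_transporter"),
                                 p_heavy = NULL,
                                 seed = 1L) {
  scenario <- match.arg(scenario)
  classes <- c("sigF", "sigG", "sigE", "sigK", "vegetative")
  if (is.null(names(n_proteins)) || !all(names(n_proteins) %in% classes)) {
    stop_param("n_proteins must be named with classes among: %s",
               paste(classes, collapse = ", "))
  }
  full <- stats::setNames(rep(0, length(classes)), classes)
  full[names(n_proteins)] <- n_proteins
  check_number(full, "n_proteins", min = 0, len = length(classes))
  # background = nonspecific incorporation via residual arginine transport,
  # ~12% of sporulation-specific peptides in the transporter-less control
  defaults <- switch(scenario,
    control = list(mother_cell = 0.12, forespore = 0.12, background = 0.12),
    mc_transporter = list(mother_cell = 0.30, forespore = 0.25, background = 0.12),
    fs_transporter = list(mother_cell = 0.14, forespore = 0.162, background = 0.12)
  )
  if (!is.null(p_heavy)) {
    bad <- setdiff(names(p_heavy), names(defaults))
    if (length(bad)) stop_param("unknown p_heavy entries: %s", paste(bad, collapse = ", "))
    defaults[names(p_heavy)] <- p_heavy
  }
  for (nm in names(defaults)) {
    check_number(defaults[[nm]], paste0("p_heavy$", nm), min = 0, max = 1)
  }
  norm_spec <- function(spec, name, min_allowed) {
    if (is.numeric(spec) && length(spec) == 1) {
      spec <- list(dist = "fixed", value = spec)
    }
    if (!is.list(spec) || is.null(spec$dist)) stop_param("`%s` must be a distribution spec", name)
    if (!spec$dist %in% c("fixed", "poisson")) stop_param("`%s`: unsupported dist '%s'", name, spec$dist)
    spec$min <- max(spec$min %||% min_allowed, min_allowed)
    spec
  }
  structure(
    list(n_proteins = full,
         peptides_per_protein = norm_spec(peptides_per_protein,
                                          "peptides_per_protein", 1),
         arg_per_peptide = norm_spec(arg_per_peptide, "arg_per_peptide", 0),
         scenario = scenario, p_heavy = defaults, seed = as.integer(seed)),
    class = "peptide_table_params"
  )
}

draw_spec <- function(spec, n) {
  x <- switch(spec$dist,
    fixed = rep(as.integer(spec$value), n),
    poisson = stats::rpois(n, spec$lambda)
  )
  as.integer(pmax(x, spec$min))
}

#' Generate a ground-truthed SILAC peptide table
#'
#' Emits one record per peptide with a surrogate sequence, source protein,
#' regulon set, arginine count and heavy flag, plus the regulon map of the
#' surrogate proteome and the exact labeling probabilities used. The heavy
#' flag of each arginine-containing peptide is drawn from the probability
#' of its protein's compartment (vegetative proteins use the background
#' probability); peptides without arginine are never heavy. A small
#' fraction of vegetative proteins carries an additional sporulation
#' regulon (exercising the vegetative-precedence rule) and a few forespore
#' proteins belong to both sigF and sigG.
#'
#' @param params A [peptide_table_params()].
#' @return List with `peptides` (data frame: `peptide_id`, `sequence`,
#'   `protein_id`, `regulons`, `arg_count`, `heavy`), `regulon_map`
#'   (data frame: `protein_id`, `regulons`), and `truth` (labeling
#'   probabilities per compartment, scenario, per-protein compartments).
#' @export
generate_peptide_table <- function(params) {
  stopifnot(inherits(params, "peptide_table_params"))
  with_seed(params$seed, {
    np <- params$n_proteins
    classes <- rep(names(np), np)
    n_prot <- length(classes)
    protein_id <- sprintf("SQP%04d", seq_len(n_prot))
    regulons <- character(n_prot)
    for (i in seq_len(n_prot)) {
      regulons[i] <- switch(classes[i],
        sigF = if (stats::runif(1) < 0.05) "SigF,SigG" else "SigF",
        sigG = "SigG",
        sigE = "SigE",
        sigK = "SigK",
        vegetative = {
          base <- sample(c("SigA", "SigH", "Spo0A"), 1)
          # some vegetative genes are additionally induced in sporulation;
          # the vegetative assignment takes precedence
          if (stats::runif(1) < 0.10) paste0(base, ",", sample(c("SigE", "SigF"), 1)) else base
        }
      )
    }
    compartment <- c(sigF = "forespore", sigG = "forespore",
                     sigE = "mother_cell", sigK = "mother_cell",
                     vegetative = "vegetative")[classes]
    n_pep <- draw_spec(params$peptides_per_protein, n_prot)
    pep_protein <- rep(seq_len(n_prot), n_pep)
    total <- length(pep_protein)
    arg_count <- draw_spec(params$arg_per_peptide, total)
    p <- ifelse(compartment[pep_protein] == "vegetative",
                params$p_heavy$background,
                ifelse(compartment[pep_protein] == "forespore",
                       params$p_heavy$forespore, params$p_heavy$mother_cell))
    heavy <- arg_count >= 1 & stats::runif(total) < p
    # surrogate tryptic sequences: 12-mer body of non-arginine residues plus
    # the peptide's arginines; records look like peptides, not used
    # quantitatively
    aa <- strsplit("ACDEFGHIKLMNPQSTVWY", "")[[1]]
    body <- do.call(paste0, as.data.frame(
      matrix(sample(aa, total * 12L, replace = TRUE), total, 12L),
      stringsAsFactors = FALSE))
    sequence <- paste0(body, strrep("R", arg_count))
    peptides <- data.frame(
      peptide_id = sprintf("PEP%06d", seq_len(total)),
      sequence = sequence,
      protein_id = protein_id[pep_protein],
      regulons = regulons[pep_protein],
      arg_count = arg_count,
      heavy = heavy
    )
    regulon_map <- data.frame(protein_id = protein_id, regulons = regulons)
    truth <- list(
      p_heavy = params$p_heavy, scenario = params$scenario,
      protein_compartment = stats::setNames(compartment, protein_id),
      n_peptides = total
    )
    list(peptides = peptides, regulon_map = regulon_map, truth = truth)
  })
}

#' Write / read a peptide table as CSV
#'
#' @param peptides Peptide data frame (see [generate_peptide_table()]).
#' @param path CSV path.
#' @return `path` (write) or the parsed data frame (read).
#' @export
write_peptide_table <- function(peptides, path) {
  utils::write.csv(peptides, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peptide_table
#' @param aliases Named character vector mapping required column names
#'   (`peptide`, `protein`, `arg_count`, `heavy`) to the file's columns.
#' @export
read_peptide_table <- function(path,
                               aliases = c(peptide = "peptide_id",
                                           protein = "protein_id",
                                           arg_count = "arg_count",
                                           heavy = "heavy")) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("peptide", "protein", "arg_count", "heavy")
  missing_alias <- setdiff(need, names(aliases))
  if (length(missing_alias)) {
    stop_param("aliases must cover columns: %s", paste(need, collapse = ", "))
  }
  absent <- setdiff(unname(aliases[need]), names(df))
  if (length(absent)) {
    stop_param("peptide table lacks column(s): %s", paste(absent, collapse = ", "))
  }
  out <- data.frame(
    peptide_id = df[[aliases[["peptide"]]]],
    protein_id = df[[aliases[["protein"]]]],
    arg_count = as.integer(df[[aliases[["arg_count"]]]]),
    heavy = as.logical(df[[aliases[["heavy"]]]])
  )
  if ("sequence" %in% names(df)) out$sequence <- df$sequence
  out
}

#' Write / read a regulon map as TSV
#'
#' Two columns: `protein_id` and comma-separated `regulons`.
#'
#' @param regulon_map Data frame with `protein_id`, `regulons`.
#' @param path TSV path.
#' @return `path` (write) or the parsed data frame (read).
#' @export
write_regulon_map <- function(regulon_map, path) {
  utils::write.table(regulon_map, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_regulon_map
#' @export
read_regulon_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("protein_id", "regulons") %in% names(df))) {
    stop_param("regulon map needs columns protein_id, regulons")
  }
  if (anyDuplicated(df$protein_id)) {
    stop_param("every protein must appear exactly once in the regulon map")
  }
  df
}
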