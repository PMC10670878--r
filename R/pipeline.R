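#' Validate a pipeline run configuration
#'
#' A run configuration is a list (usually read from YAML) with `seed`,
#' `output_dir` and a list of `stages`; each stage has a `stage` name among
#' `simulate-images`, `simulate-frap`, `simulate-peptides`, `segment`,
#' `ratio`, `depletion`, `boncat`, `phase`, `frap`, `flip`, `silac`, an
#' optional unique `name`, and stage parameters. Validation runs before any
#' computation: schema violations (unknown stages, high threshold not above
#' low, probabilities outside `[0, 1]`) raise an error and nothing is
#' written.
#'
#' @param config List or YAML file path.
#' @return The normalized config list, invisibly on error-free validation.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$stages) || !length(config$stages)) {
    stop_param("config must be a list with a nonempty `stages` list")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "."
  known <- c("simulate-images", "simulate-frap", "simulate-peptides",
             "segment", "ratio", "depletion", "boncat", "phase",
             "frap", "flip", "silac")
  seen <- character(0)
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage) || !st$stage %in% known) {
      stop_param("stage %d: unknown stage '%s' (known: %s)", i,
                 st$stage %||% "<missing>", paste(known, collapse = ", "))
    }
    st$name <- st$name %||% sprintf("stage%02d_%s", i, gsub("-", "_", st$stage))
    if (st$name %in% seen) stop_param("duplicate stage name '%s'", st$name)
    seen <- c(seen, st$name)
    hq <- st$high_quantile %||% 0.995
    lq <- st$low_quantile %||% 0.95
    if (st$stage %in% c("segment", "ratio", "depletion", "boncat", "phase") &&
        hq <= lq) {
      stop_param("stage '%s': high_quantile (%g) must exceed low_quantile (%g)",
                 st$name, hq, lq)
    }
    if (st$stage == "simulate-peptides" && !is.null(st$params$p_heavy)) {
      for (p in unlist(st$params$p_heavy)) {
        if (!is.numeric(p) || p < 0 || p > 1) {
          stop_param("stage '%s': p_heavy values must lie in [0, 1]", st$name)
        }
      }
    }
    config$stages[[i]] <- st
  }
  invisible(config)
}

seg_from_stack <- function(stack, st) {
  hq <- st$high_quantile %||% 0.995
  lq <- st$low_quantile %||% 0.95
  high <- if (!is.null(st$high_absolute)) threshold_absolute(st$high_absolute) else threshold_quantile(hq)
  low <- if (!is.null(st$low_absolute)) threshold_absolute(st$low_absolute) else threshold_quantile(lq)
  min_area <- st$min_area %||% 20
  parts <- segment_membrane(stack, high, low, min_area)
  mc <- derive_mother_cells(parts$whole_cells, parts$forespores, stack,
                            min_area = min_area)
  pair_sporangia(parts$forespores, mc,
                 max_distance = st$max_distance %||% 3,
                 max_angle = st$max_angle %||% 30)
}

resolve_input <- function(st, registry, what = "input") {
  key <- st[[what]]
  if (is.null(key)) stop_param("stage '%s' needs an `%s`", st$name, what)
  if (!is.null(registry[[key]])) return(registry[[key]])
  if (file.exists(key)) return(key)
  stop_param("stage '%s': %s '%s' is neither a prior stage name nor a file",
             st$name, what, key)
}

#' Run an end-to-end analysis pipeline
#'
#' Executes the configured stages in order, wiring simulator outputs into
#' analysis stages by stage name, and writes a run manifest recording the
#' package version, config hash, seed, per-stage record counts and output
#' file hashes. Rerunning an identical config and seed reproduces identical
#' outputs.
#'
#' @param config List or YAML path (see [validate_run_config()]).
#' @param output_dir Optional override of the config's output directory.
#' @return The manifest list, invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config_path <- if (is.character(config)) config else NULL
  config <- validate_run_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- list() # stage name -> primary output path
  manifest <- list(
    tool = "sporoquant",
    version = as.character(utils::packageVersion("sporoquant")),
    config_hash = if (!is.null(config_path)) md5_of_file(config_path) else NA,
    seed = config$seed,
    stages = list()
  )
  for (st in config$stages) {
    prefix <- file.path(out_dir, st$name)
    seed <- as.integer(st$seed %||% config$seed)
    res <- switch(st$stage,
      "simulate-images" = {
        params <- do.call(sporangium_image_params,
                          c(st$params %||% list(), list(seed = seed)))
        if (!is.null(st$n_frames)) {
          sim <- generate_timelapse(params, st$depletion_rate %||% 0,
                                    st$n_frames)
          paths <- character(0)
          for (f in seq_along(sim$frames)) {
            p <- sprintf("%s_frame%03d.tif", prefix, f)
            write_image_stack(sim$frames[[f]], p)
            paths <- c(paths, p)
          }
          write_ground_truth(sim$truth, paste0(prefix, "_truth"))
          registry[[st$name]] <- paths
          list(outputs = paths, records = length(paths))
        } else {
          sim <- generate_sporangium_image(params)
          p <- paste0(prefix, ".tif")
          write_image_stack(sim$stack, p)
          write_ground_truth(sim$truth, paste0(prefix, "_truth"))
          registry[[st$name]] <- p
          list(outputs = p, records = nrow(sim$truth$cells))
        }
      },
      "simulate-frap" = {
        params <- do.call(photobleach_params,
                          c(st$params %||% list(), list(seed = seed)))
        sim <- generate_photobleach_trace(params)
        p <- paste0(prefix, ".csv")
        write_photobleach_trace(sim$trace, p)
        jsonlite::write_json(sim$truth[c("k", "rate", "v_fs", "v_mc", "c0",
                                         "acq_loss", "cfr_plateau")],
                             paste0(prefix, "_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        registry[[st$name]] <- p
        list(outputs = p, records = nrow(sim$trace))
      },
      "simulate-peptides" = {
        params <- do.call(peptide_table_params,
                          c(st$params %||% list(), list(seed = seed)))
        sim <- generate_peptide_table(params)
        p <- paste0(prefix, "_peptides.csv")
        write_peptide_table(sim$peptides, p)
        rp <- paste0(prefix, "_regulons.tsv")
        write_regulon_map(sim$regulon_map, rp)
        jsonlite::write_json(sim$truth[c("p_heavy", "scenario", "n_peptides")],
                             paste0(prefix, "_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        registry[[st$name]] <- p
        registry[[paste0(st$name, "_regulons")]] <- rp
        list(outputs = c(p, rp), records = nrow(sim$peptides))
      },
      "segment" = {
        stack <- read_image_stack(resolve_input(st, registry))
        seg <- seg_from_stack(stack, st)
        write_segmentation(seg, prefix)
        registry[[st$name]] <- paste0(prefix, "_pairs.csv")
        list(outputs = paste0(prefix, c("_pairs.csv", "_fs_labels.tif",
                                        "_mc_labels.tif")),
             records = nrow(seg$pairs))
      },
      "ratio" = {
        stack <- read_image_stack(resolve_input(st, registry))
        seg <- seg_from_stack(stack, st)
        bg <- estimate_background(stack, st$channel %||% "reporter")
        rt <- concentration_ratio(seg, stack, bg,
                                  channel = st$channel %||% "reporter",
                                  volume_mode = isTRUE(st$volume_mode))
        p <- paste0(prefix, "_ratios.csv")
        utils::write.csv(rt, p, row.names = FALSE)
        jsonlite::write_json(ratio_box_stats(rt$ratio),
                             paste0(prefix, "_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        registry[[st$name]] <- p
        list(outputs = c(p, paste0(prefix, "_summary.json")),
             records = nrow(rt))
      },
      "depletion" = {
        paths <- resolve_input(st, registry)
        frames <- lapply(paths, read_image_stack)
        series <- depletion_timecourse(frames)
        p <- paste0(prefix, "_depletion.csv")
        long <- do.call(rbind, lapply(seq_along(series), function(i) {
          cbind(track = i, as.data.frame(series[[i]]))
        }))
        utils::write.csv(long, p, row.names = FALSE)
        registry[[st$name]] <- p
        list(outputs = p, records = length(series))
      },
      "boncat" = {
        stack <- read_image_stack(resolve_input(st, registry))
        seg <- seg_from_stack(stack, st)
        bg <- estimate_background(stack, st$channel %||% "reporter")
        ch <- get_channel(stack, st$channel %||% "reporter")
        vals <- lapply(seq_len(nrow(seg$pairs)), function(i) {
          pr <- seg$pairs[i, ]
          m <- boncat_quantify(ch,
                               object_mask(seg$forespores, pr$fs_label),
                               object_mask(seg$mother_cells, pr$mc_label),
                               bg$mask,
                               st$reference_medians %||% list(fs = 1, mc = 1))
          data.frame(fs_label = pr$fs_label, mc_label = pr$mc_label,
                     fs_value = m$fs_value, mc_value = m$mc_value)
        })
        vals <- do.call(rbind, vals)
        p <- paste0(prefix, "_boncat.csv")
        utils::write.csv(vals, p, row.names = FALSE)
        registry[[st$name]] <- p
        list(outputs = p, records = nrow(vals))
      },
      "phase" = {
        stack <- read_image_stack(resolve_input(st, registry))
        seg <- seg_from_stack(stack, st)
        # use the permeable-dye channel for forespore candidates so engulfed
        # forespores (absent from the membrane channel) are still scored
        eng <- classify_engulfed(stack, seg$forespores)
        ps <- phase_bright_score(stack, seg$forespores, eng,
                                 threshold = st$threshold %||% 0.1)
        p <- paste0(prefix, "_phase.csv")
        utils::write.csv(ps, p, row.names = FALSE)
        registry[[st$name]] <- p
        list(outputs = p, records = nrow(ps))
      },
      "frap" = {
        trace <- read_photobleach_trace(resolve_input(st, registry))
        cfr <- compute_cfr(trace)
        p <- paste0(prefix, "_cfr.csv")
        utils::write.csv(as.data.frame(cfr), p, row.names = FALSE)
        outs <- p
        if (!is.null(st$v_fs) && !is.null(st$v_mc)) {
          fit <- estimate_exchange_rate(cfr, st$v_fs, st$v_mc)
          fp <- paste0(prefix, "_fit.json")
          jsonlite::write_json(fit[c("k_hat", "rate_hat", "plateau",
                                     "residual", "converged")],
                               fp, auto_unbox = TRUE, digits = NA)
          outs <- c(outs, fp)
        }
        registry[[st$name]] <- p
        list(outputs = outs, records = nrow(cfr))
      },
      "flip" = {
        trace <- read_photobleach_trace(resolve_input(st, registry))
        loss <- fit_acquisition_loss(trace)
        flip <- compute_flip(trace, loss)
        p <- paste0(prefix, "_flip.csv")
        utils::write.csv(as.data.frame(flip), p, row.names = FALSE)
        lp <- paste0(prefix, "_loss_curve.csv")
        utils::write.csv(as.data.frame(loss), lp, row.names = FALSE)
        registry[[st$name]] <- p
        list(outputs = c(p, lp), records = nrow(flip))
      },
      "silac" = {
        pep <- resolve_input(st, registry, "peptides")
        reg <- resolve_input(st, registry, "regulons")
        ctl <- if (!is.null(st$control)) resolve_input(st, registry, "control") else NULL
        res <- silac_summarize(pep, reg, ctl)
        p <- paste0(prefix, "_summary.csv")
        utils::write.csv(as.data.frame(res$summary), p, row.names = FALSE)
        jsonlite::write_json(
          list(summary = res$summary,
               filter_report = as.list(res$filter_report),
               folds = res$folds),
          paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA
        )
        registry[[st$name]] <- p
        list(outputs = c(p, paste0(prefix, "_summary.json")),
             records = sum(res$summary$n_peptides[res$summary$level == "compartment"]))
      }
    )
    manifest$stages[[st$name]] <- list(
      stage = st$stage, seed = seed, records = res$records,
      outputs = as.list(stats::setNames(
        vapply(res$outputs, md5_of_file, character(1)), basename(res$outputs)))
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
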