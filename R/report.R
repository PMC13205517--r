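#' One-way ANOVA on leading-component per-subject ISC across conditions
#'
#' A thin reporting helper: tests whether per-subject ISC of a chosen
#' component differs across conditions with a standard one-way ANOVA
#' (`df1 = conditions - 1`, `df2 = total - conditions`).
#'
#' @param isc_by_condition Either a named list of numeric vectors (one per
#'   condition, per-subject ISC values) or a data frame with columns
#'   `condition` and `isc`.
#' @param component Component index used only for labelling (default 1).
#' @return A one-row tibble: `component`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `n`. Groups with identical constant values in all
#'   conditions give `statistic = 0` or a degenerate fit flagged by
#'   `p_value = NA`.
#' @export
condition_anova <- function(isc_by_condition, component = 1) {
  if (is.data.frame(isc_by_condition)) {
    df <- tibble(condition = as.character(isc_by_condition$condition),
                 isc = isc_by_condition$isc)
  } else {
    df <- purrr::map_dfr(names(isc_by_condition), function(nm) {
      tibble(condition = nm, isc = as.numeric(isc_by_condition[[nm]]))
    })
  }
  counts <- table(df$condition)
  if (length(counts) < 2) abort("at least 2 conditions are required")
  if (any(counts < 2)) {
    abort(sprintf("condition(s) with fewer than 2 values: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  if (var(df$isc) < .Machine$double.eps) {
    # all values identical: no variance to partition
    return(tibble(component = component, statistic = NA_real_,
                  df1 = length(counts) - 1, df2 = nrow(df) - length(counts),
                  p_value = NA_real_, n = nrow(df)))
  }
  fit <- aov(isc ~ condition, data = df)
  s <- summary(fit)[[1]]
  f_val <- s[["F value"]][1]
  tibble(component = component,
         statistic = if (is.finite(f_val)) f_val else NA_real_,
         df1 = s[["Df"]][1], df2 = s[["Df"]][2],
         p_value = s[["Pr(>F)"]][1], n = nrow(df))
}

#' Export forward-model loadings joined to the face template
#'
#' Prepares the per-landmark loading table that facial topography plots
#' consume: one row per landmark per component, with template coordinates.
#' Requires the forward model to have exactly 68 rows (one per landmark);
#' full X/Y-channel fits (136 features) are rejected rather than silently
#' reshaped.
#'
#' @param result A `corrca_result` fitted on 68 landmark features.
#' @param template A [face_template()] tibble.
#' @param components Which components to export (default all fitted).
#' @param path Optional directory; when given, one CSV per component is
#'   written (`topoplot_C<k>.csv`).
#' @return A tibble with `component`, `landmark`, `x`, `y`, `region`,
#'   `loading`.
#' @export
export_topoplot_data <- function(result, template = face_template(),
                                 components = NULL, path = NULL) {
  stopifnot(inherits(result, "corrca_result"))
  if (nrow(result$A) != 68) {
    abort(sprintf(paste0("forward model has %d rows; facial topography ",
                         "needs exactly 68 (one per landmark) - refit on ",
                         "scalarised landmark features"),
                  nrow(result$A)))
  }
  components <- components %||% seq_len(ncol(result$A))
  out <- purrr::map_dfr(components, function(k) {
    dplyr::mutate(template, component = k, loading = result$A[, k],
                  .before = 1)
  })
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in components) {
      readr::write_csv(dplyr::filter(out, .data$component == k),
                       file.path(path, sprintf("topoplot_C%d.csv", k)))
    }
  }
  out
}

#' Run the full preprocessing and synchrony pipeline on a data folder
#'
#' Reads Trace-dialect CSVs, filters by missingness, resamples and aligns
#' per group, then runs the enabled analyses (SUSY on a chosen channel
#' and/or CorrCA on scalarised landmark features) and writes every stage's
#' outputs and effective settings into the artifact directory. Reruns with
#' the same configuration and seed reproduce every numeric artifact.
#'
#' @param data_dir Folder of input CSVs.
#' @param out_dir Artifact directory (created; stage subdirectories
#'   `processed/`, `susy/`, `corrca/`).
#' @param column_map A [trace_column_map()].
#' @param preproc A [preproc_config()].
#' @param analyses Character subset of `c("susy", "corrca")`.
#' @param susy_channel Channel for SUSY (default `"head_movement"`).
#' @param susy Optional [susy_config()]; its rate must match the channel.
#' @param corrca A [corrca_config()].
#' @param scalar_mode Scalarisation mode for CorrCA.
#' @param seed Integer seed threaded through all stochastic stages.
#' @return Invisibly, a list of per-group results (`recording_set`, and the
#'   requested `susy`/`corrca` fits) plus the exclusion table.
#' @export
run_pipeline <- function(data_dir, out_dir,
                         column_map = trace_column_map(),
                         preproc = preproc_config(),
                         analyses = c("susy", "corrca"),
                         susy_channel = "head_movement",
                         susy = NULL,
                         corrca = corrca_config(),
                         scalar_mode = "vector_norm",
                         seed = 1) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  raws <- read_trace_folder(data_dir, column_map)
  flt <- filter_by_missingness(raws, preproc)
  if (length(flt$kept) < 2) {
    abort("preproc stage failed: fewer than 2 recordings survive filtering")
  }
  groups <- group_records(flt$kept, column_map$grouping)
  results <- list()
  for (g in names(groups)) {
    if (length(groups[[g]]) < 2) {
      inform(sprintf("group '%s' has < 2 recordings; skipped", g))
      next
    }
    res <- lapply(groups[[g]], resample_to_grid, config = preproc)
    set <- align_group(res, preproc)
    gdir <- file.path(out_dir, "processed", gsub("[^A-Za-z0-9_.-]", "_", g))
    write_processed(set, gdir)
    out <- list(set = set)
    if ("susy" %in% analyses) {
      rate <- if (identical(susy_channel, "head_movement")) 1 else set$rate
      cfg <- susy %||% susy_config(rate = rate, seed = seed)
      cfg$seed <- cfg$seed %||% seed
      sres <- susy(set, config = cfg, channel = susy_channel)
      sdir <- file.path(out_dir, "susy")
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(tidy(sres),
                       file.path(sdir, sprintf("susy_%s.csv",
                                               gsub("[^A-Za-z0-9_.-]", "_",
                                                    g))))
      out$susy <- sres
    }
    if ("corrca" %in% analyses) {
      fm <- scalarize(set, mode = scalar_mode)
      cres <- corrca_fit(fm, corrca)
      cdir <- file.path(out_dir, "corrca")
      dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
      safe_g <- gsub("[^A-Za-z0-9_.-]", "_", g)
      readr::write_csv(tidy(cres),
                       file.path(cdir, sprintf("components_%s.csv", safe_g)))
      readr::write_csv(
        as_tibble(cres$subject_isc, rownames = "subject"),
        file.path(cdir, sprintf("subject_isc_%s.csv", safe_g)))
      if (!is.null(cres$windowed)) {
        readr::write_csv(cres$windowed,
                         file.path(cdir, sprintf("windowed_%s.csv", safe_g)))
      }
      readr::write_csv(export_topoplot_data(cres),
                       file.path(cdir, sprintf("topoplot_%s.csv", safe_g)))
      out$corrca <- cres
    }
    results[[g]] <- out
  }
  manifest <- list(
    column_map = unclass(column_map), preproc = unclass(preproc),
    analyses = analyses, susy_channel = susy_channel,
    corrca = unclass(corrca), scalar_mode = scalar_mode, seed = seed,
    groups = names(results),
    excluded = if (nrow(flt$excluded) > 0) flt$excluded else NULL,
    package_version = as.character(utils::packageVersion("facesync"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "pipeline_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(results, list(excluded = flt$excluded)))
}
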