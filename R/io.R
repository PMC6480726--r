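# Spectrum file formats (two-column CSV and JCAMP-DX AFFN) and the
# end-to-end pipeline driver.

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Write a spectrum to disk
#'
#' `"csv"` writes a two-column (ppm, intensity) file with acquisition
#' metadata in `#`-prefixed header comments. `"jcamp"` writes a minimal
#' JCAMP-DX 4.24 file with an AFFN `XYDATA=(X++(Y..Y))` block. Both
#' formats use fixed float formatting, so identical spectra produce
#' byte-identical files.
#'
#' @param spectrum An `nmr_spectrum` (real part written).
#' @param path Output path.
#' @param format `"csv"` or `"jcamp"`.
#' @return The path, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("csv", "jcamp")) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  format <- match.arg(format)
  x <- spectrum$ppm
  y <- Re(spectrum$intensity)
  meta <- spectrum$meta
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_lfnmr("cannot write to '", path, "': ", conditionMessage(e),
               class = "lfnmr_io_error"))
  on.exit(close(con))
  put <- function(...) writeLines(paste0(...), con, sep = "\n")
  if (format == "csv") {
    if (!is.null(meta$field_MHz)) put("# field_MHz: ", fmt_num(meta$field_MHz))
    if (!is.null(meta$n_scans)) put("# n_scans: ", meta$n_scans)
    put("ppm,intensity")
    put(paste0(fmt_num(x), ",", fmt_num(y)))
  } else {
    put("##TITLE=lfnmr spectrum")
    put("##JCAMP-DX=4.24")
    put("##DATA TYPE=NMR SPECTRUM")
    if (!is.null(meta$field_MHz))
      put("##.OBSERVE FREQUENCY=", fmt_num(meta$field_MHz))
    if (!is.null(meta$n_scans)) put("##$NSCANS=", meta$n_scans)
    put("##XUNITS=PPM")
    put("##YUNITS=ARBITRARY UNITS")
    put("##XFACTOR=1")
    put("##YFACTOR=1")
    put("##FIRSTX=", fmt_num(x[1]))
    put("##LASTX=", fmt_num(x[length(x)]))
    put("##NPOINTS=", length(x))
    put("##XYDATA=(X++(Y..Y))")
    per_line <- 6L
    for (i in seq(1L, length(x), by = per_line)) {
      j <- min(i + per_line - 1L, length(x))
      put(paste(c(fmt_num(x[i]), fmt_num(y[i:j])), collapse = " "))
    }
    put("##END=")
  }
  invisible(path)
}

#' Read a spectrum from disk
#'
#' Parses the two formats written by [write_spectrum()]: two-column CSV
#' (with optional `#` metadata comments) and JCAMP-DX with an AFFN
#' `XYDATA=(X++(Y..Y))` block. Axes are normalised to ascending ppm.
#' Malformed files raise an error naming the offending line.
#'
#' @param path Input path.
#' @param format `"csv"`, `"jcamp"`, or `"auto"` (by file content).
#' @return An `nmr_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_lfnmr("file not found: ", path, class = "lfnmr_io_error")
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(startsWith(lines, "##TITLE"))) "jcamp" else "csv"
  if (format == "csv") read_spectrum_csv(lines, path)
  else read_spectrum_jcamp(lines, path)
}

read_spectrum_csv <- function(lines, path) {
  meta <- list()
  for (ln in lines[startsWith(lines, "#")]) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("field_MHz:", kv))
      meta$field_MHz <- as.numeric(sub(".*field_MHz:\\s*", "", kv))
    if (grepl("n_scans:", kv))
      meta$n_scans <- as.integer(sub(".*n_scans:\\s*", "", kv))
  }
  body <- which(!startsWith(lines, "#"))
  header <- body[1]
  data_lines <- lines[body[-1]]
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop_lfnmr("malformed CSV at line ", body[bad[1] + 1L], " of ", path,
               class = "lfnmr_io_error")
  x <- as.numeric(vapply(parts, `[`, "", 1L))
  y <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(x) || anyNA(y))
    stop_lfnmr("non-numeric value at line ",
               body[which(is.na(x) | is.na(y))[1] + 1L], " of ", path,
               class = "lfnmr_io_error")
  nmr_spectrum(x, y, meta)
}

read_spectrum_jcamp <- function(lines, path) {
  meta <- list()
  get_field <- function(key) {
    i <- grep(paste0("^", key, "="), lines, fixed = FALSE)
    if (!length(i)) return(NULL)
    sub(paste0("^", key, "="), "", lines[i[1]])
  }
  of <- get_field("##\\.OBSERVE FREQUENCY")
  if (!is.null(of)) meta$field_MHz <- as.numeric(of)
  ns <- get_field("##\\$NSCANS")
  if (!is.null(ns)) meta$n_scans <- as.integer(ns)
  xf <- as.numeric(get_field("##XFACTOR") %||% "1")
  yf <- as.numeric(get_field("##YFACTOR") %||% "1")
  start <- grep("^##XYDATA", lines)
  if (!length(start))
    stop_lfnmr("no XYDATA block in ", path, class = "lfnmr_io_error")
  end <- grep("^##END", lines)
  end <- if (length(end)) end[end > start][1] else length(lines) + 1L
  block <- lines[(start + 1L):(end - 1L)]
  xs <- list(); ys <- list()
  for (k in seq_along(block)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(block[k]),
                                                 "\\s+")[[1]]))
    if (length(vals) < 2L || anyNA(vals))
      stop_lfnmr("malformed XYDATA at line ", start + k, " of ", path,
                 class = "lfnmr_io_error")
    xs[[k]] <- vals[1]
    ys[[k]] <- vals[-1]
  }
  npt <- as.integer(get_field("##NPOINTS") %||% NA)
  y <- unlist(ys) * yf
  x_starts <- unlist(xs) * xf
  counts <- lengths(ys)
  firstx <- as.numeric(get_field("##FIRSTX") %||% x_starts[1])
  lastx <- as.numeric(get_field("##LASTX") %||% NA)
  n <- length(y)
  if (!is.na(npt) && npt != n)
    stop_lfnmr("NPOINTS (", npt, ") disagrees with XYDATA length (", n,
               ") in ", path, class = "lfnmr_io_error")
  dx <- if (!is.na(lastx)) (lastx - firstx) / (n - 1) else
    (x_starts[2] - x_starts[1]) / counts[1]
  x <- firstx + dx * (seq_len(n) - 1L)
  nmr_spectrum(x, y, meta)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, quantify and stats stages (and the
#' four-method comparison when requested) from one configuration, writing
#' every artefact plus a manifest recording the package version, seed,
#' parameters and MD5 hashes of all outputs. Reruns with the same seed
#' produce identical hashes.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognised elements: `seed` (required), `outdir`, `acquisition`
#'   (arguments to [acquisition_config()]), `cohort` (`n_diabetic`,
#'   `n_control`), `stats` (`n_features`, `n_splits`, `n_orthogonal`,
#'   `k_folds`), `compare` (logical; run the four-method agreement stage),
#'   `bucket_table` (optional CSV path).
#' @return Invisibly, a list with the cohort, feature matrices, model
#'   results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop_lfnmr("config must set a seed", class = "lfnmr_validation_error")
  outdir <- config$outdir %||% "lfnmr_run"
  buckets <- if (!is.null(config$bucket_table)) {
    if (!file.exists(config$bucket_table))
      stop_lfnmr("bucket table not found: ", config$bucket_table,
                 class = "lfnmr_io_error")
    bucket_table(utils::read.csv(config$bucket_table, comment.char = "#"))
  } else default_bucket_table()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  acq <- do.call(acquisition_config, config$acquisition %||% list())
  spec <- diabetes_cohort_spec(
    n_diabetic = config$cohort$n_diabetic %||% 10,
    n_control = config$cohort$n_control %||% 14)
  seeds <- derive_seeds(config$seed, 4L)

  cohort <- generate_cohort(spec, acq, seed = seeds[[1]])
  utils::write.csv(cohort$truth, file.path(outdir, "truth.csv"),
                   row.names = FALSE)

  fm <- build_feature_matrix(cohort$spectra, buckets)
  fm_tsp <- normalize_features(fm, "tsp")
  write_feature_matrix(fm_tsp, file.path(outdir, "feature_matrix_tsp.csv"))

  st <- config$stats %||% list()
  scaled <- pareto_scale(glog_transform(fm_tsp))
  tt <- ttest_fdr(fm_tsp, cohort$groups)
  pca <- nmr_pca(scaled)
  opls <- oplsda_fit(scaled, cohort$groups,
                     st$n_orthogonal %||% 1)
  opls$Q2 <- cv_q2(scaled, cohort$groups, st$k_folds %||% 10,
                   st$n_orthogonal %||% 1, seed = seeds[[2]])
  roc <- mccv_svm_roc(fm_tsp, cohort$groups,
                      n_features = st$n_features %||% 10,
                      n_splits = st$n_splits %||% 100, seed = seeds[[3]])
  rf <- random_forest_classify(fm_tsp, cohort$groups, seed = seeds[[4]])

  utils::write.csv(tt, file.path(outdir, "ttests.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(fm), pca$scores),
                   file.path(outdir, "pca_scores.csv"), row.names = FALSE)
  utils::write.csv(roc$mean_roc, file.path(outdir, "roc_points.csv"),
                   row.names = FALSE)
  summary <- list(R2X = opls$R2X, R2Y = opls$R2Y, Q2 = opls$Q2,
                  auroc = roc$auroc, rf_oob_accuracy = rf$oob_accuracy,
                  pca_components = pca$n_components,
                  pca_variance = pca$total_explained)
  compare_res <- NULL
  if (isTRUE(config$compare)) {
    mc <- generate_method_comparison(seed = seeds[[1]])
    utils::write.csv(mc, file.path(outdir, "method_comparison.csv"),
                     row.names = FALSE)
    vc <- variance_components_anova(mc)
    summary$p_participant <- vc$p_participant
    summary$p_method <- vc$p_method
    compare_res <- vc
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "lfnmr",
    version = as.character(utils::packageVersion("lfnmr")),
    seed = config$seed,
    parameters = config,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(sort(outputs))), basename(sort(outputs)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, feature_matrix = fm_tsp, ttests = tt,
                 pca = pca, oplsda = opls, roc = roc, rf = rf,
                 compare = compare_res, manifest = manifest,
                 outdir = outdir))
}

#' Write a feature matrix as CSV with a state header
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("# state: ",
                    paste(state_of(fm), collapse = " > ")), con)
  writeLines(paste(c("sample", colnames(fm)), collapse = ","), con)
  for (i in seq_len(nrow(fm)))
    writeLines(paste(c(rownames(fm)[i], fmt_num(fm[i, ])),
                     collapse = ","), con)
  invisible(path)
}
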