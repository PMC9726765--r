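# End-to-end orchestration: simulate or ingest, estimate prevalence and
# weights per scheme, compute SMPHs, run the validation battery, and
# write a manifest of every artifact.

.fmt_num_df <- function(d) {
  for (j in seq_along(d))
    if (is.numeric(d[[j]]) && !is.integer(d[[j]]))
      d[[j]] <- signif(d[[j]], 6)  # 6 significant digits for stable diffs
  d
}

.write_artifact <- function(obj, path) {
  if (is.data.frame(obj)) {
    utils::write.csv(.fmt_num_df(as.data.frame(obj)), path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  path
}

#' Run the full WAHE pipeline
#'
#' Orchestrates: (optionally) simulating survey microdata and a life
#' table, estimating prevalence and well-being weights for each requested
#' scheme, computing LE/HE/WAHE per stratum, summarizing across
#' countries, and running the validation battery per sex. All artifacts
#' are written as CSV/JSON under \code{out_dir} together with the
#' resolved configuration and a manifest with content hashes.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{out_dir}{output directory (created if absent); mandatory.}
#'     \item{seed}{integer seed for simulation (default 1).}
#'     \item{simulate}{list of \code{\link{generator_config}} overrides;
#'       if absent, \code{data} and \code{lifetable} paths are required.}
#'     \item{data, column_map}{survey CSV path (+ optional column map)
#'       when not simulating.}
#'     \item{lifetable}{life-table CSV path when not simulating.}
#'     \item{schemes}{character vector of scheme names (default all
#'       four).}
#'     \item{age_anchor}{anchor age x (default 15).}
#'     \item{alpha}{slope-significance level (default 0.05).}
#'     \item{min_cell}{sparse-state threshold (default 30).}
#'     \item{external}{optional CSV of external SMPH values
#'       (country, sex, measure, scheme, value_years) merged into the
#'       validation battery.}
#'   }
#' @return Invisibly, a list with \code{out_dir}, \code{manifest}
#'   (data.frame of file names and md5 hashes) and \code{smph} (the tidy
#'   SMPH table).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("precondition error: config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(seed = 1L, schemes = c("chronic", "gali", "srh", "multi"),
         age_anchor = 15, alpha = 0.05, min_cell = 30L),
    config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  emit <- function(obj, name) {
    p <- file.path(cfg$out_dir, name)
    .write_artifact(obj, p)
    artifacts <<- c(artifacts, p)
    message("wrote ", p)
    p
  }

  if (!is.null(cfg$simulate)) {
    gen_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    gen <- do.call(generator_config, gen_args)
    message("simulating survey microdata (seed ", gen$seed, ")")
    data <- generate_survey(gen)
    lts <- list()
    for (co in gen$countries) for (sx in gen$sexes)
      lts[[paste(co, sx, sep = ":")]] <- generate_lifetable(gen, co, sx)
    emit(data, "survey.csv")
    lt_path <- file.path(cfg$out_dir, "lifetable.csv")
    write_lifetable(lts, lt_path)
    artifacts <- c(artifacts, lt_path)
  } else {
    if (is.null(cfg$data) || is.null(cfg$lifetable))
      stop("config must provide either 'simulate' or both 'data' and 'lifetable'")
    for (p in c(cfg$data, cfg$lifetable))
      if (!file.exists(p))
        stop(sprintf("precondition error: input file '%s' not found", p))
    data <- read_microdata(cfg$data, column_map = cfg$column_map)
    rep <- validation_report(data)
    if (nrow(rep)) emit(rep, "validation_report.csv")
    lts <- read_lifetable(cfg$lifetable)
  }

  prevs <- list(); wts <- list()
  for (sc_name in cfg$schemes) {
    sc <- health_scheme(sc_name)
    message("scheme '", sc_name, "': prevalence + weights")
    prevs[[sc_name]] <- estimate_prevalence(data, sc)
    wts[[sc_name]] <- estimate_weights(data, sc, min_cell = cfg$min_cell)
    emit(prevs[[sc_name]], sprintf("prevalence_%s.csv", sc_name))
    emit(wts[[sc_name]], sprintf("weights_%s.csv", sc_name))
  }

  smph <- compute_smph(lts, prevs, wts, x = cfg$age_anchor)
  if (!is.null(cfg$external)) {
    ext <- utils::read.csv(cfg$external, stringsAsFactors = FALSE)
    smph <- rbind(smph, ext[, c("country", "sex", "measure", "scheme",
                                "value_years")])
  }
  emit(smph, "smph.csv")
  if (length(unique(smph$country)) >= 2L)
    emit(summarize_smph(smph), "smph_summary.csv")

  for (sx in unique(smph$sex)) {
    M <- smph_matrix(smph, sx)
    if (nrow(M) >= 4L && ncol(M) >= 2L) {
      v <- validate_smph(M, alpha = cfg$alpha)
      emit(list(
        spearman = list(rho = v$spearman$rho, p = v$spearman$p),
        icc = if (!is.null(v$icc)) unclass(v$icc),
        loo = if (!is.null(v$loo)) v$loo$by_excluded,
        agreement = lapply(v$agreement, function(a)
          a[c("labels", "n", "bias", "sd_diff", "slope", "intercept",
              "slope_p", "loa_mode", "outside_count")])
      ), sprintf("validation_%s.json", sx))
    }
  }

  cfg_path <- file.path(cfg$out_dir, "resolved_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  artifacts <- c(artifacts, cfg_path)
  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(out_dir = cfg$out_dir, manifest = manifest, smph = smph))
}
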