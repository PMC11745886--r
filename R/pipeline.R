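#' Pipeline configuration
#'
#' @param workdir Directory holding the manifest-referenced images and
#'   annotation sidecars, and receiving the outputs.
#' @param manifest Path to the cohort manifest CSV.
#' @param sfa An [sfa_config].
#' @param pixel_size_mm Calibration applied to every image.
#' @param alpha Significance level for the group comparisons.
#' @param seed Integer seed recorded in (and hashing into) the report.
#' @param out_results,out_stats,out_report Output file names, resolved
#'   relative to `workdir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(workdir, manifest = file.path(workdir, "manifest.csv"),
                            sfa = sfa_config(), pixel_size_mm = 0.0625,
                            alpha = 0.05, seed = 1L,
                            out_results = "results.csv",
                            out_stats = "group_stats.json",
                            out_report = "report.md") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(workdir = workdir, manifest = manifest, sfa = sfa,
                 pixel_size_mm = pixel_size_mm, alpha = alpha,
                 seed = as.integer(seed),
                 out_results = out_results, out_stats = out_stats,
                 out_report = out_report),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

anova_summary_row <- function(res, site, measure, limbs) {
  g <- res$groups
  row <- data.frame(site = site, measure = measure, stringsAsFactors = FALSE)
  for (l in limbs) {
    i <- match(l, g$label)
    row[[paste0(l, "_mean")]] <- g$mean[i]
  }
  row$f <- res$f
  row$df_between <- res$df_between
  row$df_within <- res$df_within
  row$p <- res$p
  row$eta_squared <- res$eta_squared
  row$eta_lo <- res$eta_ci[1]
  row$eta_hi <- res$eta_ci[2]
  row
}

#' Run the full analysis pipeline
#'
#' simulate (externally) -> SFA -> thickness -> group statistics: reads the
#' manifest, measures ROI PSFR and tendon thickness on every image, writes a
#' per-image results CSV, per-site ANOVA results as JSON, and a markdown
#' report laid out as a three-sites by three-limbs grid of mean (sd) with
#' effect sizes and p-values. Deterministic for fixed inputs and seed; the
#' report embeds the package version and a hash of the configuration.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with `results` (per-image data.frame), `stats`
#'   (per-site/measure data.frame), `posthoc`, and the three output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  manifest <- read_manifest(config$manifest)
  base <- dirname(config$manifest)

  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    ipath <- file.path(base, r$image)
    apath <- file.path(base, r$annotations)
    if (!file.exists(ipath)) {
      stop("[stage sfa] manifest row ", i, " (", r$subject_id, "/", r$limb,
           "/", r$site, "): image file missing: ", ipath)
    }
    img <- read_image(ipath, pixel_size_mm = config$pixel_size_mm)
    ann <- read_annotations(apath)
    sfa_res <- roi_psfr(img, ann, config$sfa)
    th <- if (r$site == "insertion") thickness_at_insertion(ann, img)
          else thickness_at_center(ann, img)
    rows[[i]] <- data.frame(subject_id = r$subject_id, group = r$group,
                            limb = r$limb, site = r$site,
                            n_kernels = sfa_res$n_kernels,
                            n_valid = sfa_res$n_valid,
                            roi_psfr = sfa_res$roi_psfr,
                            thickness_mm = th$value_mm,
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  res_path <- file.path(config$workdir, config$out_results)
  write_results(results, res_path)

  limbs <- c("control", "non_paretic", "paretic")
  sites <- intersect(c("insertion", "above2cm", "above4cm"),
                     unique(results$site))
  stat_rows <- list(); posthoc <- list()
  for (measure in c("thickness_mm", "roi_psfr")) {
    for (site in sites) {
      sub <- results[results$site == site, ]
      grp <- split(sub[[measure]], factor(sub$limb, levels = limbs))
      grp <- grp[lengths(grp) >= 2L]
      if (length(grp) < 2L) next
      res <- anova_oneway(grp)
      stat_rows[[length(stat_rows) + 1L]] <-
        anova_summary_row(res, site, measure, names(grp))
      ph <- res$posthoc
      ph$site <- site; ph$measure <- measure
      posthoc[[length(posthoc) + 1L]] <- ph
    }
  }
  stats_df <- do.call(rbind, lapply(stat_rows, function(x) {
    x[setdiff(unique(unlist(lapply(stat_rows, names))), names(x))] <- NA
    x
  }))
  posthoc_df <- do.call(rbind, posthoc)
  stats_path <- file.path(config$workdir, config$out_stats)
  jsonlite::write_json(list(anova = stats_df, posthoc = posthoc_df,
                            alpha = config$alpha),
                       stats_path, auto_unbox = TRUE, digits = NA)

  report_path <- file.path(config$workdir, config$out_report)
  writeLines(render_report(results, stats_df, config), report_path)
  invisible(list(results = results, stats = stats_df, posthoc = posthoc_df,
                 results_path = res_path, stats_path = stats_path,
                 report_path = report_path))
}

render_report <- function(results, stats_df, config) {
  fmt_cell <- function(sub, limb, measure) {
    v <- sub[[measure]][sub$limb == limb]
    if (length(v) == 0) return("--")
    sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
  }
  lines <- c("# Tendon morphology report", "",
             sprintf("package tendonsfa %s; config hash %s; seed %d",
                     as.character(utils::packageVersion("tendonsfa")),
                     config_hash(config), config$seed),
             "",
             "| Measure | Site | Control | Non-paretic | Paretic | eta^2 | p |",
             "|---|---|---|---|---|---|---|")
  for (measure in c("thickness_mm", "roi_psfr")) {
    mlab <- if (measure == "thickness_mm") "Thickness (mm)" else "PSFR (mm^-1)"
    for (site in c("above4cm", "above2cm", "insertion")) {
      sub <- results[results$site == site, ]
      if (nrow(sub) == 0) next
      st <- stats_df[stats_df$site == site & stats_df$measure == measure, ]
      sig <- nrow(st) == 1 && is.finite(st$p) && st$p <= config$alpha
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %s | %s%s |",
        mlab, site,
        fmt_cell(sub, "control", measure),
        fmt_cell(sub, "non_paretic", measure),
        fmt_cell(sub, "paretic", measure),
        if (nrow(st) == 1) sprintf("%.2f", st$eta_squared) else "--",
        if (nrow(st) == 1) sprintf("%.3f", st$p) else "--",
        if (sig) " *" else ""))
    }
  }
  c(lines, "", "`*` significant at the configured alpha.")
}

#' Generate the bundled demonstration cohort
#'
#' Emulates the study design (15 stroke subjects contributing paretic and
#' non-paretic limbs, 19 controls contributing the control limb, three sites
#' each: 147 images) with the default effect structure.
#'
#' @param workdir Writable output directory.
#' @param seed Master seed.
#' @param n_stroke,n_control Group sizes.
#' @return Path to the generated manifest CSV.
#' @export
make_demo <- function(workdir, seed = 7L, n_stroke = 15L, n_control = 19L) {
  ok <- tryCatch({
    dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
    file.access(workdir, 2) == 0
  }, error = function(e) FALSE)
  if (!isTRUE(ok)) stop("workdir is not writable: ", workdir)
  generate_cohort(n_stroke, n_control, seed = seed, dir = workdir)$manifest
}
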