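#' Build an experiment configuration
#'
#' Bundles everything a study run needs: the phantom, the acquisition design
#' (15 views over a 15-degree arc by default, thinned to 7 for the half-dose
#' arm), the per-view fluence, the four algorithms' parameters and the seeds.
#' The study defaults reconstruct SART and ASD-POCS for 5 iterations,
#' MLEM for 2, ASD-POCS with alpha = 0.002 and ng = 25, and run 10 phantom
#' seeds so summary rows carry means and standard errors.
#'
#' @param phantom a \linkS4class{PhantomSpec}.
#' @param geometry geometry constants, see \code{\link{geometryConfig}}.
#' @param n_views,arc_span normal-acquisition design.
#' @param fluence_per_view incident photons per pixel per view.
#' @param fbp_kernels FBP kernels to run (\code{"ramp"},
#'   \code{"shepp_logan"}).
#' @param sart,mlem,asdpocs algorithm parameter objects.
#' @param ssim \linkS4class{SSIMParams} for the MSSIM comparison.
#' @param seeds integer phantom seeds.
#' @param profile_half_length FWHM profile half length, mm.
#' @param output_dir directory the drivers write reports into ("" disables
#'   writing).
#' @return an \linkS4class{ExperimentConfig}.
#' @export
experimentConfig <- function(phantom = phantomSpec(),
                             geometry = geometryConfig(),
                             n_views = 15L, arc_span = 15,
                             fluence_per_view = 1e4,
                             fbp_kernels = c("ramp", "shepp_logan"),
                             sart = sartParams(), mlem = mlemParams(),
                             asdpocs = asdpocsParams(), ssim = ssimParams(),
                             seeds = 0:9, profile_half_length = 2,
                             output_dir = "") {
  new("ExperimentConfig", phantom = phantom, geometry = geometry,
      n_views = as.integer(n_views), arc_span = arc_span,
      fluence_per_view = fluence_per_view, fbp_kernels = fbp_kernels,
      sart = sart, mlem = mlem, asdpocs = asdpocs, ssim = ssim,
      seeds = as.integer(seeds), profile_half_length = profile_half_length,
      output_dir = output_dir)
}

.opForConfig <- function(config) {
  spec <- config@phantom
  dims <- as.integer(round(spec@volume_extent / spec@voxel_size))
  systemOperator(makeGeometry(config@n_views, config@arc_span, config@geometry),
                 dims, spec@voxel_size)
}

.specWithSeed <- function(spec, seed) {
  spec@seed <- as.integer(seed)
  spec
}

# One normal acquisition per seed; the acquisition noise seed is derived
# deterministically from the phantom seed.
.simulateForSeed <- function(config, seed, op = .opForConfig(config)) {
  vol <- buildPhantom(.specWithSeed(config@phantom, seed))
  ps15 <- simulateAcquisition(vol, op, config@fluence_per_view,
                              seed = as.integer(seed) + 5000L)
  list(volume = vol, ps15 = ps15, op = op)
}

.variantList <- function(config) {
  v <- list()
  for (k in config@fbp_kernels)
    v[[paste0("fbp_", k)]] <- list(algorithm = "fbp", kernel = k)
  v$sart <- list(algorithm = "sart", kernel = NA_character_)
  v$mlem <- list(algorithm = "mlem", kernel = NA_character_)
  v$asd_pocs <- list(algorithm = "asd_pocs", kernel = NA_character_)
  v
}

.reconVariant <- function(variant, ps, op, config) {
  switch(variant$algorithm,
         fbp = fbp(ps, op, fbpParams(variant$kernel)),
         sart = sart(ps, op, config@sart),
         mlem = mlem(ps, op, config@mlem),
         asd_pocs = asdPocs(ps, op, config@asdpocs),
         stop("unknown algorithm variant"))
}

.mmToVoxel <- function(xy_mm, spec) {
  dims <- as.integer(round(spec@volume_extent / spec@voxel_size))
  cen <- xy_mm + spec@volume_extent[1:2] / 2
  pmin(pmax(as.integer(ceiling(cen / spec@voxel_size[1:2] - 1e-9)), 1L),
       dims[1:2])
}

.metricRow <- function(seed, variant_name, variant, n_views, metric, target,
                       value, flag) {
  data.frame(seed = seed, algorithm = variant_name, kernel = variant$kernel,
             n_views = n_views, metric = metric, target = target,
             value = value, flag = flag, stringsAsFactors = FALSE)
}

# FWHM per MC, CNR and background SD per mass for one reconstruction.
.insertMetrics <- function(recon, phantom, config, seed, variant_name,
                           variant, n_views) {
  spec <- config@phantom
  reg <- insertRegistry(phantom)
  vs <- spec@voxel_size
  rows <- list()
  for (n in which(reg$type == "mc")) {
    pf <- profileFWHM(recon, c(reg$ix[n], reg$iy[n], reg$iz[n]),
                      config@profile_half_length, vs)
    rows[[length(rows) + 1L]] <- .metricRow(
      seed, variant_name, variant, n_views, "fwhm", reg$id[n], pf$fwhm,
      if (is.na(pf$fwhm)) paste(unique(pf$flags), collapse = "+") else "ok")
  }
  bg_ctr <- .mmToVoxel(spec@bg_reference, spec)
  for (n in which(reg$type == "mass")) {
    size_px <- featureRoiPx(reg$diameter_mm[n], vs[1])
    froi <- roiAround(c(reg$ix[n], reg$iy[n]), size_px, reg$iz[n])
    broi <- roiAround(bg_ctr, size_px, reg$iz[n])
    cc <- cnr(recon, froi, broi)
    rows[[length(rows) + 1L]] <- .metricRow(
      seed, variant_name, variant, n_views, "cnr", reg$id[n], cc$cnr, cc$flag)
    rows[[length(rows) + 1L]] <- .metricRow(
      seed, variant_name, variant, n_views, "sigma_bg", reg$id[n],
      cc$sigma_bg, cc$flag)
  }
  do.call(rbind, rows)
}

.seIfMany <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_

#' Run the normal-versus-half projection comparison
#'
#' For every configured seed, one normal 15-view acquisition is simulated;
#' the 7-view half acquisition is derived from it by
#' \code{\link{thinProjections}} (never re-simulated).  All algorithm
#' variants (FBP with each configured kernel, SART, MLEM, ASD-POCS) are run
#' at both view counts with the configured iteration defaults, and FWHM (per
#' MC size), CNR and background SD (per mass size) are measured in the
#' in-focus plane.  The MSSIM of the in-focus plane is computed per variant
#' with the 15-view reconstruction as reference and the 7-view one as
#' objective, so the MSSIM rows exist only for the 7-view arm.  Per-cell
#' measurement failures are flagged; the report is emitted regardless.
#'
#' @param config an \linkS4class{ExperimentConfig}.
#' @return a \linkS4class{ComparisonReport}; if \code{config@output_dir} is
#'   nonempty, records and summary are also written there as CSV.
#' @export
runProjectionComparison <- function(config) {
  validObject(config)
  op15 <- .opForConfig(config)
  variants <- .variantList(config)
  records <- list()
  for (seed in config@seeds) {
    sim <- .simulateForSeed(config, seed, op15)
    ps7 <- thinProjections(sim$ps15)
    op7 <- systemOperator(ps7@geometry, op15@volume_shape, op15@voxel_size,
                          op15@interpolation, op15@volume_origin)
    focus <- insertRegistry(sim$volume)$iz[1]
    for (vn in names(variants)) {
      va <- variants[[vn]]
      r15 <- tryCatch(.reconVariant(va, sim$ps15, op15, config),
                      error = function(e) e)
      r7 <- tryCatch(.reconVariant(va, ps7, op7, config),
                     error = function(e) e)
      for (arm in list(list(r = r15, nv = config@n_views),
                       list(r = r7, nv = ps7@geometry@n_views))) {
        if (inherits(arm$r, "error")) {
          records[[length(records) + 1L]] <- .metricRow(
            seed, vn, va, arm$nv, "error", "all", NA_real_,
            conditionMessage(arm$r))
        } else {
          records[[length(records) + 1L]] <- .insertMetrics(
            arm$r, sim$volume, config, seed, vn, va, arm$nv)
        }
      }
      if (!inherits(r15, "error") && !inherits(r7, "error")) {
        sres <- ssim(reconData(r15)[, , focus], reconData(r7)[, , focus],
                     config@ssim,
                     reference_id = sprintf("%s_%dviews", vn, config@n_views),
                     objective_id = sprintf("%s_%dviews", vn,
                                            ps7@geometry@n_views))
        records[[length(records) + 1L]] <- .metricRow(
          seed, vn, va, ps7@geometry@n_views, "mssim", "in_focus_plane",
          sres@mssim, "ok")
      }
    }
  }
  records <- do.call(rbind, records)
  report <- new("ComparisonReport", records = records,
                summary = .summarizeComparison(records, config),
                seeds = config@seeds)
  if (nzchar(config@output_dir)) {
    dir.create(config@output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(config@output_dir, "comparison_records.csv"),
              row.names = FALSE)
    write.csv(report@summary,
              file.path(config@output_dir, "comparison_summary.csv"),
              row.names = FALSE)
  }
  report
}

# Across-seed means and standard errors per (variant, metric, target), with
# the 15-to-7-view rate of change of the means.
.summarizeComparison <- function(records, config) {
  full <- config@n_views
  half <- (full - 1L) %/% 2L
  keys <- unique(records[records$metric != "error",
                         c("algorithm", "metric", "target")])
  out <- list()
  for (r in seq_len(nrow(keys))) {
    sel <- records$algorithm == keys$algorithm[r] &
      records$metric == keys$metric[r] & records$target == keys$target[r]
    v15 <- records$value[sel & records$n_views == full]
    v7 <- records$value[sel & records$n_views == half]
    m15 <- if (length(v15)) mean(v15, na.rm = TRUE) else NA_real_
    m7 <- if (length(v7)) mean(v7, na.rm = TRUE) else NA_real_
    roc <- if (!is.na(m15) && !is.na(m7) && m15 != 0)
      100 * (m7 - m15) / m15 else NA_real_
    out[[r]] <- data.frame(
      algorithm = keys$algorithm[r], metric = keys$metric[r],
      target = keys$target[r], mean_15 = m15,
      se_15 = if (length(v15)) .seIfMany(v15[!is.na(v15)]) else NA_real_,
      mean_7 = m7,
      se_7 = if (length(v7)) .seIfMany(v7[!is.na(v7)]) else NA_real_,
      rate_of_change_pct = roc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport: %d records over %d seeds\n",
              nrow(object@records), length(object@seeds)))
  print(object@summary, digits = 4)
  invisible(object)
})

#' Sweep the ASD-POCS TV hyperparameters
#'
#' For every (alpha, ng) grid cell, the configured seeds are simulated
#' (normal acquisition), reconstructed with ASD-POCS, and the FWHM, CNR and
#' background-SD metrics recorded -- the experiment design used to justify
#' the default choice alpha = 0.002, ng = 25.  Larger alpha smooths harder,
#' trading FWHM for CNR.  Cell failures are recorded and the sweep
#' continues.
#'
#' @param config an \linkS4class{ExperimentConfig}.
#' @param alpha_grid,ng_grid nonempty parameter grids.
#' @return data.frame with one row per (seed, alpha, ng, metric, target).
#' @export
runParameterSweep <- function(config, alpha_grid, ng_grid) {
  validObject(config)
  if (length(alpha_grid) < 1L || length(ng_grid) < 1L)
    stop("alpha_grid and ng_grid must be nonempty")
  op <- .opForConfig(config)
  base <- config@asdpocs
  rows <- list()
  for (seed in config@seeds) {
    sim <- .simulateForSeed(config, seed, op)
    for (alpha in alpha_grid) for (ng in ng_grid) {
      cell <- tryCatch({
        p <- asdpocsParams(n_iterations = base@n_iterations, beta = base@beta,
                           beta_red = base@beta_red, alpha = alpha,
                           alpha_red = base@alpha_red,
                           gamma_max = base@gamma_max, ng = ng,
                           epsilon = base@epsilon,
                           smoothing_delta = base@smoothing_delta)
        recon <- asdPocs(sim$ps15, op, p)
        m <- .insertMetrics(recon, sim$volume, config, seed, "asd_pocs",
                            list(kernel = NA_character_), config@n_views)
        m$alpha <- alpha
        m$ng <- as.integer(ng)
        m
      }, error = function(e) data.frame(
        seed = seed, algorithm = "asd_pocs", kernel = NA_character_,
        n_views = config@n_views, metric = "error", target = "all",
        value = NA_real_, flag = conditionMessage(e), alpha = alpha,
        ng = as.integer(ng), stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  if (nzchar(config@output_dir)) {
    dir.create(config@output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(config@output_dir, "parameter_sweep.csv"),
              row.names = FALSE)
  }
  out
}

#' Iteration-convergence study
#'
#' Runs SART, MLEM and ASD-POCS on the normal acquisition of the first
#' configured seed for \code{max_iterations} iterations and records, at every
#' iteration, the RMSE and the universal quality index between the previous
#' and current iterate volumes -- the selection procedure behind the
#' iteration-count defaults (5 for SART/ASD-POCS, 2 for MLEM).
#'
#' @param config an \linkS4class{ExperimentConfig}.
#' @param max_iterations at least 2.
#' @return data.frame with columns algorithm, iteration, rmse_prev_curr,
#'   qi_prev_curr.
#' @export
runConvergenceStudy <- function(config, max_iterations = 8L) {
  validObject(config)
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 2L) stop("max_iterations must be >= 2")
  op <- .opForConfig(config)
  sim <- .simulateForSeed(config, config@seeds[1], op)
  runs <- list(
    sart = sart(sim$ps15, op,
                sartParams(n_iterations = max_iterations,
                           relaxation = config@sart@relaxation[1],
                           nonnegativity = config@sart@nonnegativity),
                keep_iterates = TRUE),
    mlem = mlem(sim$ps15, op,
                mlemParams(n_iterations = max_iterations,
                           epsilon_guard = config@mlem@epsilon_guard),
                keep_iterates = TRUE),
    asd_pocs = asdPocs(sim$ps15, op,
                       asdpocsParams(n_iterations = max_iterations,
                                     beta = config@asdpocs@beta,
                                     beta_red = config@asdpocs@beta_red,
                                     alpha = config@asdpocs@alpha,
                                     alpha_red = config@asdpocs@alpha_red,
                                     gamma_max = config@asdpocs@gamma_max,
                                     ng = config@asdpocs@ng,
                                     epsilon = config@asdpocs@epsilon),
                       keep_iterates = TRUE))
  rows <- list()
  for (algo in names(runs)) {
    its <- attr(runs[[algo]], "iterates")
    for (i in 2:max_iterations) {
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = algo, iteration = i,
        rmse_prev_curr = rmse(its[[i - 1]], its[[i]]),
        qi_prev_curr = qi(its[[i - 1]], its[[i]])$qi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (nzchar(config@output_dir)) {
    dir.create(config@output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(config@output_dir, "convergence_study.csv"),
              row.names = FALSE)
  }
  out
}
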