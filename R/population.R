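# Population study orchestration: factorial simulation plan over
# tibiae x {PEEK, titanium} x {gait, squat}, batch execution, and the
# linear mixed model of micromotion on patient factors.

#' Pipeline configuration for cohort simulations
#'
#' Bundles the geometry, contact, solver and metric settings used for
#' every model in a cohort run. `edge_scale` trades mesh resolution for
#' runtime on the shared configuration surface.
#'
#' @param edge_scale global edge-length multiplier (1 = the 2.0-2.5 mm
#'   reference meshes; desk-scale cohorts run coarser).
#' @param n_cycles loading cycles per activity (micromotion is read from
#'   the final cycle).
#' @param use_cpd refine the landmark frame by rigid CPD of the surface
#'   against the canonical template.
#' @param reference_bodyweight kg; the 1514 N reference peak applies at
#'   this bodyweight.
#' @param tibia geometry spec, see [tibia_spec()].
#' @param geometry a [geometry_config()] (built from `edge_scale` when
#'   omitted).
#' @param contact a [contact_parameters()].
#' @param catalog an [implant_catalog()].
#' @param control a [solver_control()].
#' @param gap_threshold,threshold micromotion metric settings (mm, um).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(edge_scale = 5,
                            n_cycles = 4,
                            use_cpd = TRUE,
                            reference_bodyweight = 75,
                            tibia = tibia_spec(),
                            geometry = NULL,
                            contact = contact_parameters(),
                            catalog = implant_catalog(),
                            control = solver_control(tol_rel = 1e-7,
                                                     max_iter = 30,
                                                     max_bisect = 6),
                            gap_threshold = 0.5,
                            threshold = 112) {
  geometry <- geometry %||% geometry_config(edge_scale = edge_scale)
  structure(list(edge_scale = edge_scale, n_cycles = n_cycles,
                 use_cpd = use_cpd,
                 reference_bodyweight = reference_bodyweight,
                 tibia = tibia, geometry = geometry, contact = contact,
                 catalog = catalog, control = control,
                 gap_threshold = gap_threshold, threshold = threshold),
            class = "pipeline_config")
}

#' Build the factorial simulation plan
#'
#' Full factorial over tibiae x tray materials x activities with
#' deterministic ordering and per-entry seeds.
#'
#' @param cohort a `patient_cohort` (one row per tibia).
#' @param seed base seed; entry seeds are derived per tibia.
#' @param materials,activities factor levels.
#' @return a `simulation_plan` data.frame; `nrow = n_tibiae * 4` by
#'   default.
#' @export
build_plan <- function(cohort, seed = 1,
                       materials = c("PEEK", "titanium"),
                       activities = c("gait", "squat")) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    tid <- sprintf("%s_%s", cohort$patient_id[i], cohort$side[i])
    for (m in materials) for (a in activities) {
      rows[[length(rows) + 1]] <- data.frame(
        model_id = tid, patient_id = cohort$patient_id[i],
        side = cohort$side[i], tray_material = m, activity = a,
        seed = derive_seed(seed, tid),
        stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  key <- paste(plan$model_id, plan$tray_material, plan$activity)
  stopifnot(!anyDuplicated(key))
  plan$status <- "pending"
  class(plan) <- c("simulation_plan", "data.frame")
  plan
}

#' Reconstruct and mesh one tibia
#'
#' Runs the geometry stages for a single tibia: synthetic anatomy, frame
#' assignment, optional CPD alignment refinement against the canonical
#' template, bone cuts, tray sizing, and tetrahedralization of bone (with
#' the peg bore) and implant.
#'
#' @param patient one cohort row.
#' @param config a [pipeline_config()].
#' @param seed integer seed for this tibia.
#' @return a `reconstruction`: tibia, frame, selection, `bone_mesh`,
#'   `implant_mesh`, cut solid.
#' @export
reconstruct_tibia <- function(patient, config = pipeline_config(), seed = 1) {
  tibia <- generate_tibia(patient, config$tibia, seed = seed)
  frame <- assign_frame(tibia)
  align <- NULL
  if (config$use_cpd) {
    tmpl <- generate_tibia(list(height = 1.71, side = patient$side),
                           config$tibia, seed = 0, apply_pose_noise = FALSE)
    src <- apply_transform(frame_to_local(frame), tibia$surface$vertices)
    sub <- function(x, n = 140) x[seq(1, nrow(x), length.out = n), , drop = FALSE]
    align <- cpd_rigid(sub(src), sub(tmpl$surface$vertices), tol = 1e-7,
                       max_iter = 60)
  }
  cs <- cut_bone(tibia, frame, config$geometry, align = align)
  sel <- select_tray_size(cs$outline, config$catalog, config$geometry$max_overhang)
  entry <- config$catalog$sizes[[sel$size]]
  bore <- list(radius = entry$peg_radius, depth = entry$peg_length + 1,
               center = sel$placement$translation[1:2])
  bone_mesh <- tetrahedralize(cs, config$geometry, bore = bore)
  implant_mesh <- tetrahedralize(
    implant_volume(entry, z0 = cs$z_prox, placement = sel$placement),
    config$geometry)
  structure(list(tibia = tibia, frame = frame, align = align,
                 cut = cs, selection = sel, entry = entry,
                 bone_mesh = bone_mesh, implant_mesh = implant_mesh),
            class = "reconstruction")
}

#' Simulate one tibia under both materials and activities
#'
#' Shares the reconstruction between the four factorial arms; the virtual
#' implantation is re-run per material, each activity starts from the
#' implanted state.
#'
#' @param patient one cohort row.
#' @param config a [pipeline_config()].
#' @param seed per-tibia seed.
#' @param materials,activities arms to run.
#' @param keep_history return the interface histories as an attribute.
#' @return data.frame of result rows (one per arm).
#' @export
simulate_tibia <- function(patient, config = pipeline_config(), seed = 1,
                           materials = c("PEEK", "titanium"),
                           activities = c("gait", "squat"),
                           keep_history = FALSE) {
  rec <- reconstruct_tibia(patient, config, seed)
  tid <- sprintf("%s_%s", patient$patient_id, patient$side)
  out <- list(); hists <- list()
  for (m in materials) {
    cm <- contact_model(rec$bone_mesh, rec$implant_mesh, m, config$contact)
    st <- virtual_implantation(cm, config$control)
    for (a in activities) {
      lp <- build_load_profile(a, bodyweight = patient$weight,
                               reference_bodyweight = config$reference_bodyweight,
                               n_cycles = config$n_cycles,
                               insert_halfwidth = 0.5 * rec$entry$halfwidth,
                               insert_halfdepth = 0.5 * rec$entry$halfdepth)
      hist <- run_activity(cm, st, lp, config$control)
      ms <- micromotion_summary(hist, gap_threshold = config$gap_threshold,
                                threshold = config$threshold)
      out[[length(out) + 1]] <- data.frame(
        model_id = tid, patient_id = patient$patient_id, side = patient$side,
        gender = patient$gender, age = patient$age, bmi = patient$bmi,
        material = m, activity = a,
        peak_um = ms$peak, p95_um = ms$p95,
        frac_below_112 = ms$area_fraction_below_threshold,
        stringsAsFactors = FALSE)
      if (keep_history) hists[[paste(m, a, sep = "_")]] <- hist
    }
  }
  res <- do.call(rbind, out)
  if (keep_history) attr(res, "histories") <- hists
  res
}

#' Execute a simulation plan
#'
#' Entries are grouped by tibia (the reconstruction is shared). With a
#' `cache_dir`, completed tibiae are skipped on re-run (resumability);
#' failures are recorded per entry without aborting the cohort.
#'
#' @param plan a [build_plan()] result.
#' @param cohort the `patient_cohort` the plan was built from.
#' @param config a [pipeline_config()].
#' @param cache_dir optional directory for per-tibia result caching.
#' @param verbose print progress.
#' @return a `cohort_results` data.frame (one row per completed entry)
#'   with attribute `failures`.
#' @export
run_plan <- function(plan, cohort, config = pipeline_config(),
                     cache_dir = NULL, verbose = FALSE) {
  tibs <- unique(plan[, c("model_id", "patient_id", "side", "seed")])
  res <- list(); failures <- list()
  for (i in seq_len(nrow(tibs))) {
    tid <- tibs$model_id[i]
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0(tid, ".csv"))
    } else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      res[[i]] <- utils::read.csv(cache_file, stringsAsFactors = FALSE)
      next
    }
    prow <- cohort[cohort$patient_id == tibs$patient_id[i] &
                   cohort$side == tibs$side[i], ][1, ]
    arms <- plan[plan$model_id == tid, ]
    r <- tryCatch(
      simulate_tibia(prow, config, seed = tibs$seed[i],
                     materials = unique(arms$tray_material),
                     activities = unique(arms$activity)),
      error = function(e) e)
    if (inherits(r, "error")) {
      failures[[tid]] <- conditionMessage(r)
      if (verbose) message(sprintf("[%d/%d] %s FAILED: %s", i, nrow(tibs),
                                   tid, conditionMessage(r)))
      next
    }
    if (!is.null(cache_file)) {
      dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(r, cache_file, row.names = FALSE)
    }
    if (verbose) message(sprintf("[%d/%d] %s done (p95: %s um)", i, nrow(tibs), tid,
                                 paste(round(r$p95_um, 1), collapse = "/")))
    res[[i]] <- r
  }
  out <- do.call(rbind, res)
  if (!is.null(out)) {
    class(out) <- c("cohort_results", "data.frame")
  }
  attr(out, "failures") <- failures
  out
}

#' Fit the linear mixed model of micromotion on patient factors
#'
#' `p95 micromotion ~ gender + age + bmi` with a random intercept per
#' patient (bilateral tibiae and the four factorial arms of one patient
#' are correlated), fitted by REML through lme4. Wald 95% confidence
#' intervals and normal-approximation p-values are reported per fixed
#' effect. Material and activity can be added as fixed effects.
#'
#' @param results a `cohort_results` (or data.frame with columns
#'   `p95_um`, `gender`, `age`, `bmi`, `patient_id`).
#' @param outcome outcome column, default `"p95_um"`.
#' @param include_material,include_activity add these design factors as
#'   fixed effects.
#' @return a `micromotion_lmm`: `fixed` (estimate, se, ci_low, ci_high,
#'   p per effect), `ranef_var`, `logLik`, and the underlying `lmerMod`.
#' @export
fit_lmm <- function(results, outcome = "p95_um",
                    include_material = FALSE, include_activity = FALSE) {
  d <- as.data.frame(results)
  if (length(unique(d$patient_id)) < 2) stop("need >= 2 patients", call. = FALSE)
  for (cc in c("gender", "age", "bmi")) {
    if (length(unique(d[[cc]])) < 2) {
      stop(sprintf("singular design: covariate '%s' is constant", cc), call. = FALSE)
    }
  }
  d$gender <- factor(d$gender, levels = c("F", "M"))
  rhs <- c("gender", "age", "bmi",
           if (include_material) "material",
           if (include_activity) "activity")
  fml <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + "),
                                 "+ (1 | patient_id)"))
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  z <- sm[, "Estimate"] / sm[, "Std. Error"]
  ci <- qnorm(0.975) * sm[, "Std. Error"]
  fixed <- data.frame(
    effect = rownames(sm),
    estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
    ci_low = sm[, "Estimate"] - ci, ci_high = sm[, "Estimate"] + ci,
    p = 2 * stats::pnorm(-abs(z)),
    row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fixed = fixed,
                 ranef_var = vc$vcov[vc$grp == "patient_id"][1],
                 resid_var = vc$vcov[vc$grp == "Residual"][1],
                 logLik = as.numeric(stats::logLik(fit)),
                 model = fit),
            class = "micromotion_lmm")
}

#' @export
print.micromotion_lmm <- function(x, ...) {
  cat("Linear mixed model of micromotion (REML, random patient intercept)\n")
  f <- x$fixed
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-12s %8.3f um  (95%% CI %7.3f, %7.3f)  p = %.4g\n",
                f$effect[i], f$estimate[i], f$ci_low[i], f$ci_high[i], f$p[i]))
  }
  cat(sprintf("  patient variance %.2f, residual %.2f\n",
              x$ranef_var, x$resid_var))
  invisible(x)
}

#' Summary bundle of a cohort run
#'
#' Per material/activity distribution summaries (median, IQR, kernel
#' density samples for violin plots), per-tibia PEEK - titanium p95
#' differences, and the osseointegration threshold for plot annotation.
#'
#' @param results a `cohort_results`.
#' @param fit optional `micromotion_lmm` to attach.
#' @param threshold reference threshold, um.
#' @return a `cohort_report`.
#' @export
cohort_report <- function(results, fit = NULL, threshold = 112) {
  d <- as.data.frame(results)
  groups <- split(d, list(d$material, d$activity), drop = TRUE)
  dists <- lapply(groups, function(g) {
    x <- g$p95_um
    dens <- if (length(unique(x)) > 1) {
      k <- stats::density(x, bw = "nrd0")   # Silverman's rule
      list(x = k$x, y = k$y, degenerate = FALSE)
    } else {
      list(x = unique(x), y = Inf, degenerate = TRUE)
    }
    list(n = length(x), median = stats::median(x),
         iqr = stats::IQR(x), q1 = unname(stats::quantile(x, 0.25)),
         q3 = unname(stats::quantile(x, 0.75)), density = dens)
  })
  wide <- stats::reshape(
    d[, c("model_id", "activity", "material", "p95_um")],
    idvar = c("model_id", "activity"), timevar = "material",
    direction = "wide")
  diffs <- data.frame(model_id = wide$model_id, activity = wide$activity,
                      diff_um = wide$p95_um.PEEK - wide$p95_um.titanium)
  structure(list(distributions = dists, differences = diffs,
                 threshold = threshold, fit = fit,
                 n_models = length(unique(d$model_id))),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d tibiae\n", x$n_models))
  for (nm in names(x$distributions)) {
    s <- x$distributions[[nm]]
    cat(sprintf("  %-18s median %6.1f um  IQR %6.1f%s\n", nm, s$median, s$iqr,
                if (s$density$degenerate) "  [degenerate distribution]" else ""))
  }
  cat(sprintf("  mean PEEK - titanium p95 difference: %.1f um (threshold %g um)\n",
              mean(x$differences$diff_um), x$threshold))
  invisible(x)
}

#' Violin-style plot of the cohort micromotion distributions
#'
#' @param x a `cohort_report`.
#' @param ... ignored.
#' @export
plot.cohort_report <- function(x, ...) {
  ds <- x$distributions
  n <- length(ds)
  xr <- range(unlist(lapply(ds, function(s) s$density$x)), x$threshold)
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = xr, xaxt = "n",
                 xlab = "", ylab = "p95 micromotion (um)")
  graphics::axis(1, at = seq_len(n), labels = names(ds), las = 2, cex.axis = 0.8)
  for (i in seq_len(n)) {
    s <- ds[[i]]
    if (!s$density$degenerate) {
      w <- 0.4 * s$density$y / max(s$density$y)
      graphics::polygon(c(i - w, rev(i + w)),
                        c(s$density$x, rev(s$density$x)),
                        col = "grey85", border = "grey40")
    }
    graphics::segments(i - 0.15, s$median, i + 0.15, s$median, lwd = 2)
  }
  graphics::abline(h = x$threshold, lty = 3)
  invisible(x)
}

#' Write cohort results / read them back
#'
#' @param results a `cohort_results`.
#' @param path CSV path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("cohort_results", "data.frame")
  x
}

#' Write a mixed-model fit as JSON
#'
#' @param fit a `micromotion_lmm`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  eff <- lapply(seq_len(nrow(fit$fixed)), function(i) {
    as.list(fit$fixed[i, c("estimate", "se", "ci_low", "ci_high", "p")])
  })
  names(eff) <- fit$fixed$effect
  jsonlite::write_json(list(fixed = eff, ranef_var = fit$ranef_var,
                            resid_var = fit$resid_var, logLik = fit$logLik),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
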