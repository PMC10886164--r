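# Synthetic patient cohorts.
#
# Demographics are sampled from truncated normals matched to the published
# cohort table (mean and range only are available). BMI is sampled as a
# primary quantity together with height; weight is derived as bmi * height^2
# and the joint draw is rejected until weight also falls inside its
# configured range, so every record satisfies all four range constraints
# and bmi == weight / height^2 holds exactly.

#' Default demographics configuration
#'
#' Mirrors the study cohort: 41 patients contributing 74 tibiae, 63%% female,
#' age 63 (46--75) years, height 1.71 (1.55--1.99) m, weight 79 (52--170) kg,
#' BMI 26 (18--49) kg/m^2. Standard deviations default to range/4. The
#' bilateral probability reproduces the 74-tibiae-from-41-patients ratio.
#'
#' @return a list with elements `age`, `height`, `bmi`, `weight_range`,
#'   `p_female`, `p_bilateral`. Each distribution element is a list with
#'   `mean`, `sd`, `min`, `max`.
#' @export
demographics_default <- function() {
  list(
    age    = list(mean = 63,   sd = (75 - 46) / 4,    min = 46,   max = 75),
    height = list(mean = 1.71, sd = (1.99 - 1.55) / 4, min = 1.55, max = 1.99),
    bmi    = list(mean = 26,   sd = (49 - 18) / 4,    min = 18,   max = 49),
    weight_range = c(52, 170),
    p_female = 26 / 41,
    p_bilateral = 33 / 41
  )
}

check_range <- function(d, name) {
  if (!all(c("mean", "sd", "min", "max") %in% names(d))) {
    stop(sprintf("demographics entry '%s' needs mean, sd, min, max", name),
         call. = FALSE)
  }
  if (d$min > d$max) {
    stop(sprintf("invalid range for '%s': min > max", name), call. = FALSE)
  }
  if (d$min == d$max) {
    stop(sprintf("degenerate range for '%s'", name), call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample a synthetic patient cohort
#'
#' Draws `n_patients` patients and expands them to one record per tibia
#' (patients are bilateral with probability `config$p_bilateral`). Sampling
#' is deterministic for a given `seed` and does not disturb the caller's
#' RNG state.
#'
#' @param config demographics specification, see [demographics_default()].
#' @param n_patients number of patients (>= 1).
#' @param seed integer seed.
#' @return a `patient_cohort` data.frame with one row per tibia and columns
#'   `patient_id`, `side`, `gender`, `age`, `height`, `weight`, `bmi`.
#' @export
sample_cohort <- function(config = demographics_default(), n_patients, seed) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  check_range(config$age, "age")
  check_range(config$height, "height")
  check_range(config$bmi, "bmi")
  wr <- config$weight_range
  if (wr[1] > wr[2]) stop("invalid range for 'weight': min > max", call. = FALSE)

  with_seed(seed, {
    n <- n_patients
    age <- rtruncnorm(n, config$age$mean, config$age$sd,
                      config$age$min, config$age$max)
    gender <- ifelse(stats::runif(n) < config$p_female, "F", "M")

    height <- numeric(n)
    bmi <- numeric(n)
    weight <- numeric(n)
    todo <- seq_len(n)
    # rejection on the derived weight keeps every record inside all ranges
    while (length(todo) > 0) {
      m <- length(todo)
      h <- rtruncnorm(m, config$height$mean, config$height$sd,
                      config$height$min, config$height$max)
      b <- rtruncnorm(m, config$bmi$mean, config$bmi$sd,
                      config$bmi$min, config$bmi$max)
      w <- b * h^2
      ok <- w >= wr[1] & w <= wr[2]
      idx <- todo[ok]
      height[idx] <- h[ok]
      bmi[idx] <- b[ok]
      weight[idx] <- w[ok]
      todo <- todo[!ok]
    }

    bilateral <- stats::runif(n) < config$p_bilateral
    single_side <- ifelse(stats::runif(n) < 0.5, "left", "right")

    rows <- lapply(seq_len(n), function(i) {
      sides <- if (bilateral[i]) c("left", "right") else single_side[i]
      data.frame(
        patient_id = sprintf("P%03d", i),
        side = sides,
        gender = gender[i],
        age = age[i],
        height = height[i],
        weight = weight[i],
        bmi = weight[i] / height[i]^2,
        stringsAsFactors = FALSE
      )
    })
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    class(cohort) <- c("patient_cohort", "data.frame")
    cohort
  })
}

#' @export
print.patient_cohort <- function(x, ...) {
  np <- length(unique(x$patient_id))
  cat(sprintf("Synthetic cohort: %d tibiae from %d patients\n", nrow(x), np))
  cat(sprintf("  gender: %d F / %d M (patients)\n",
              sum(!duplicated(x$patient_id) & x$gender == "F"),
              sum(!duplicated(x$patient_id) & x$gender == "M")))
  cat(sprintf("  age  %.0f (%.0f-%.0f)  bmi %.1f (%.1f-%.1f)\n",
              mean(x$age), min(x$age), max(x$age),
              mean(x$bmi), min(x$bmi), max(x$bmi)))
  invisible(x)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a `patient_cohort`.
#' @param path file path.
#' @return `read_cohort_csv` returns a `patient_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "side", "gender", "age", "height", "weight", "bmi")
  if (!all(need %in% names(x))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  class(x) <- c("patient_cohort", "data.frame")
  x
}
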