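#' Cohort configuration for the patient simulator
#'
#' Group-wise means and SDs for the five ULM vascular parameters and the
#' clinical covariates of an azoospermia cohort. Vascular defaults are the
#' NOA/OA group statistics of the clinical cohort the pipeline targets
#' (n = 36 NOA / 58 OA): mean velocity 3.130 (1.024) vs 3.214 (0.813) mm/s,
#' tortuosity 2.759 (0.368) vs 2.742 (0.343), diameter 143.1 (31.3) vs
#' 183.6 (37.1) um, vessel density 0.392 (0.148) vs 0.542 (0.143), fractal
#' number 1.793 (0.063) vs 1.852 (0.057). Clinical covariate distributions
#' (FSH, LH, T, age, testicular volume) are plausible choices consistent with
#' the reported group differences (elevated FSH/LH and smaller volume in NOA);
#' see the methods vignette.
#'
#' @param n_noa,n_oa group sizes (each >= 2).
#' @param noa,oa named lists of `c(mean, sd)` pairs per parameter; entries
#'   override the defaults. Names: `mean_velocity`, `mean_tortuosity`,
#'   `mean_diameter`, `vessel_density`, `fractal_number`, `fsh`, `lh`, `t`,
#'   `age`, `testis_volume`.
#' @param correlation optional symmetric positive semi-definite matrix (rows
#'   and columns named by parameters) imposed within each group through a
#'   Gaussian copula; `NULL` draws independently.
#' @param seed integer RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_noa = 36L, n_oa = 58L,
                          noa = list(), oa = list(),
                          correlation = NULL, seed = 1L) {
  if (n_noa < 2L || n_oa < 2L) abort("need at least 2 patients per group")
  base_noa <- list(
    mean_velocity = c(3.130, 1.024), mean_tortuosity = c(2.759, 0.368),
    mean_diameter = c(143.1, 31.3), vessel_density = c(0.392, 0.148),
    fractal_number = c(1.793, 0.063),
    fsh = c(18, 8), lh = c(8, 3.5), t = c(3.5, 1.5),
    age = c(28, 5), testis_volume = c(8, 3))
  base_oa <- list(
    mean_velocity = c(3.214, 0.813), mean_tortuosity = c(2.742, 0.343),
    mean_diameter = c(183.6, 37.1), vessel_density = c(0.542, 0.143),
    fractal_number = c(1.852, 0.057),
    fsh = c(4.5, 1.8), lh = c(4, 1.5), t = c(4.2, 1.5),
    age = c(32, 5), testis_volume = c(13, 4))
  noa <- utils::modifyList(base_noa, noa)
  oa <- utils::modifyList(base_oa, oa)
  for (g in list(noa, oa))
    if (any(vapply(g, function(v) v[2] < 0, logical(1))))
      abort("parameter SDs must be >= 0")
  if (!is.null(correlation)) {
    if (!isSymmetric(unname(correlation)))
      abort("correlation matrix must be symmetric")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    bad <- ev[ev < -1e-10]
    if (length(bad))
      abort(sprintf(
        "correlation matrix is not positive semi-definite (eigenvalue %.4g)",
        min(bad)))
  }
  structure(list(n_noa = as.integer(n_noa), n_oa = as.integer(n_oa),
                 noa = noa, oa = oa, correlation = correlation,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# per-parameter truncation bounds keeping draws physically meaningful
cohort_bounds <- function() list(
  mean_velocity = c(0, Inf), mean_tortuosity = c(1, Inf),
  mean_diameter = c(0, Inf), vessel_density = c(0, 1),
  fractal_number = c(1, 2),
  fsh = c(0, Inf), lh = c(0, Inf), t = c(0, Inf),
  age = c(18, 70), testis_volume = c(0.5, Inf))

#' Simulate a synthetic NOA/OA patient cohort
#'
#' Draws per-group parameters from truncated normal distributions at the
#' configured means/SDs (Gaussian copula when a correlation matrix is given),
#' attaches group labels and derives testis dimensions consistent with the
#' Lambert volume formula (length x height x width x 0.71). Reproducible
#' under the configured seed.
#'
#' @param cfg a [cohort_config()].
#' @return tibble with one row per patient: `id`, `group` (`"NOA"`/`"OA"`),
#'   clinical covariates (`fsh`, `lh`, `t`, `age`, `testis_length`,
#'   `testis_height`, `testis_width`, `testis_volume`) and the five vascular
#'   parameters.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' dplyr::count(cohort, group)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    noa <- draw_group(cfg$n_noa, cfg$noa, cfg$correlation, "NOA")
    oa <- draw_group(cfg$n_oa, cfg$oa, cfg$correlation, "OA")
    out <- dplyr::bind_rows(noa, oa)
    out$id <- sprintf("P%03d", seq_len(nrow(out)))
    # testis dimensions: aspect ratios ~ (1, 0.6, 0.5), scaled so that the
    # Lambert formula returns the drawn volume exactly
    asp <- c(1, 0.6, 0.5)
    scale <- (out$testis_volume / (0.71 * prod(asp)))^(1 / 3)
    out$testis_length <- scale * asp[1]
    out$testis_height <- scale * asp[2]
    out$testis_width <- scale * asp[3]
    dplyr::select(out, "id", "group", "fsh", "lh", "t", "age",
                  "testis_length", "testis_height", "testis_width",
                  "testis_volume", dplyr::everything())
  })
}

draw_group <- function(n, pars, correlation, label) {
  bounds <- cohort_bounds()
  vars <- names(pars)
  if (is.null(correlation)) {
    u <- matrix(runif(n * length(vars)), n, length(vars),
                dimnames = list(NULL, vars))
  } else {
    cv <- intersect(vars, rownames(correlation))
    z <- matrix(rnorm(n * length(vars)), n, length(vars),
                dimnames = list(NULL, vars))
    if (length(cv) > 1L) {
      L <- chol(correlation[cv, cv])
      z[, cv] <- matrix(rnorm(n * length(cv)), n) %*% L
    }
    u <- stats::pnorm(z)
  }
  cols <- lapply(vars, function(v) {
    m <- pars[[v]][1]; s <- pars[[v]][2]
    b <- bounds[[v]] %||% c(-Inf, Inf)
    qtruncnorm(u[, v], m, s, b[1], b[2])
  })
  names(cols) <- vars
  out <- as_tibble(cols)
  out$group <- label
  out
}

# truncated-normal quantile via the probability-integral transform
qtruncnorm <- function(p, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), length(p)))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + p * (pu - pl), mean, sd)
}
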