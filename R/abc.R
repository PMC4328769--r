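#' Prior configuration for ABC scenario choice
#'
#' Log-uniform priors in the DIYABC style. Effective-size bounds are
#' marker-specific: 1 to 400,000 diploid individuals for the RAD marker and
#' 0.25 to 100,000 for the mitochondrial marker (bounds on the fourfold
#' smaller mitochondrial effective size itself). Divergence times are drawn
#' in generations, mutation rates per site per generation (RAD 1e-8 to 1e-6
#' around a mean of 1e-7; mito 1e-7 to 1e-5 around 1e-6).
#'
#' @param marker `"rad"` or `"mito"`
#' @param ne_bounds,time_bounds,mu_bounds length-2 numeric bounds (override
#'   the marker defaults)
#' @return an object of class `prior_config`
#' @export
prior_config <- function(marker = c("rad", "mito"), ne_bounds = NULL,
                         time_bounds = c(1e3, 1e7), mu_bounds = NULL) {
  marker <- match.arg(marker)
  if (is.null(ne_bounds)) {
    ne_bounds <- if (marker == "rad") c(1, 4e5) else c(0.25, 1e5)
  }
  if (is.null(mu_bounds)) {
    mu_bounds <- if (marker == "rad") c(1e-8, 1e-6) else c(1e-7, 1e-5)
  }
  for (b in list(ne_bounds, time_bounds, mu_bounds)) {
    if (length(b) != 2 || any(b <= 0) || b[1] >= b[2]) {
      stop("bounds must be positive with lower < upper", call. = FALSE)
    }
  }
  structure(list(marker = marker, ne_bounds = ne_bounds,
                 time_bounds = time_bounds, mu_bounds = mu_bounds),
            class = "prior_config")
}

rloguniform <- function(n, lower, upper) {
  exp(runif(n, log(lower), log(upper)))
}

#' Draw scenario parameters from the prior
#'
#' Effective sizes (one per population label) and the mutation rate are
#' independent log-uniform draws; divergence times are drawn independently
#' log-uniformly and then sorted to respect the scenario's backward event
#' ordering. For the mitochondrial marker the drawn size is the
#' mitochondrial effective size and is stored on the scenario's nuclear
#' scale (x 4).
#'
#' @param config a [prior_config()]
#' @param scn a [scenario()] object
#' @param seed optional integer seed
#' @return named list with `times`, `sizes`, `mu` and `scenario` (the
#'   scenario carrying the drawn parameters)
#' @export
sample_prior <- function(config, scn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- sort(rloguniform(nrow(scn$events), config$time_bounds[1],
                            config$time_bounds[2]))
  sizes <- rloguniform(length(scn$leaves), config$ne_bounds[1],
                       config$ne_bounds[2])
  names(sizes) <- scn$leaves
  mu <- rloguniform(1, config$mu_bounds[1], config$mu_bounds[2])
  scen_sizes <- if (config$marker == "mito") sizes * 4 else sizes
  list(times = times, sizes = sizes, mu = mu,
       scenario = scenario_with_params(scn, times, scen_sizes))
}

# complete-data haplotype state for one simulated dataset (ABC fast path;
# shares the mutation/coalescent core and the summary-stat core with
# simulate_dataset() and summary_stats())
sim_state <- function(scn, design) {
  lineages <- design_lineages(design)
  tip_region <- rep(names(lineages), lineages)
  mat <- cpp_sim_loci(
    n_loci = design$n_loci,
    sample_region = match(tip_region, scn$leaves) - 1L,
    n_labels = length(scn$leaves),
    two_ne = as.numeric(design_two_ne(design, scn)),
    ev_time = scn$events$time,
    ev_from = match(scn$events$derived, scn$leaves) - 1L,
    ev_to = match(scn$events$ancestral, scn$leaves) - 1L,
    L_var = design_l_var(design), mu = design$mutation_rate,
    base_freq = design$base_freq
  )
  inds <- design_individual_labels(design)
  diploid <- design$marker == "rad"
  list(mat = mat, region = tip_region,
       individual = if (diploid) rep(inds, each = 2) else inds,
       diploid = diploid,
       col_locus = rep(seq_len(design$n_loci), each = design_l_var(design)))
}

#' Simulate an ABC reference table
#'
#' Draws `n_per_scenario` parameter sets per scenario from the prior,
#' simulates a dataset under each (same coalescent engine as
#' [simulate_dataset()], complete data) and records its summary-statistic
#' vector ([summary_stats()] layout). Per-statistic standardization
#' constants (mean, SD) are stored for the distance computations.
#'
#' @param scenarios named list of [scenario()] objects
#' @param config a [prior_config()]
#' @param design a [sample_design()] describing the observed dataset
#' @param n_per_scenario simulations per scenario
#' @param seed optional integer seed
#' @return an object of class `abc_reference_table`: tibble with `scenario`,
#'   parameter columns (`t_*`, `ne_*`, `mu`) and statistic columns
#'   (`s01..`); attributes `stat_names`, `stat_mean`, `stat_sd`
#' @export
build_reference_table <- function(scenarios, config, design, n_per_scenario,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(scenarios) < 2) stop("need at least two scenarios", call. = FALSE)
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, function(s) s$name, character(1))
  }
  regions <- names(design$samples)
  for (scn in scenarios) check_design_regions(design, scn)

  n_stats <- 4 * length(regions) + 3 * choose(length(regions), 2)
  per_scenario <- lapply(names(scenarios), function(id) {
    scn <- scenarios[[id]]
    n_par <- nrow(scn$events) + length(scn$leaves) + 1
    block <- t(vapply(seq_len(n_per_scenario), function(i) {
      draw <- sample_prior(config, scn)
      design$mutation_rate <- draw$mu
      vec <- stat_vector_core(sim_state(draw$scenario, design), regions)
      c(setNames(draw$times, paste0("t_", seq_along(draw$times))),
        setNames(draw$sizes, paste0("ne_", names(draw$sizes))),
        mu = draw$mu,
        setNames(vec, sprintf("s%02d", seq_along(vec))))
    }, numeric(n_par + n_stats)))
    dplyr::bind_cols(tibble::tibble(scenario = rep(id, n_per_scenario)),
                     tibble::as_tibble(as.data.frame(block)))
  })
  rows <- dplyr::bind_rows(per_scenario)
  stat_cols <- grep("^s[0-9]+$", names(rows), value = TRUE)
  sm <- as.matrix(rows[, stat_cols])
  structure(rows,
            stat_cols = stat_cols,
            stat_mean = colMeans(sm, na.rm = TRUE),
            stat_sd = apply(sm, 2, sd, na.rm = TRUE),
            class = c("abc_reference_table", class(tibble::tibble())))
}

#' Write or read an ABC reference table as CSV
#'
#' The CSV holds the `scenario` column, the parameter draws and the
#' statistic columns; standardization constants are recomputed on read.
#'
#' @param table an [build_reference_table()] result
#' @param path CSV file path
#' @return `read_reference_table()` returns an `abc_reference_table`
#' @export
write_reference_table <- function(table, path) {
  utils::write.csv(tibble::as_tibble(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  rows <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stat_cols <- grep("^s[0-9]+$", names(rows), value = TRUE)
  sm <- as.matrix(rows[, stat_cols])
  structure(rows,
            stat_cols = stat_cols,
            stat_mean = colMeans(sm, na.rm = TRUE),
            stat_sd = apply(sm, 2, sd, na.rm = TRUE),
            class = c("abc_reference_table", class(tibble::tibble())))
}

# standardized statistic matrix with NA sentinels imputed to the mean (0
# after standardization) plus 0/1 indicator columns for stats ever missing
standardized_stats <- function(table, observed = NULL) {
  stat_cols <- attr(table, "stat_cols")
  m <- as.matrix(tibble::as_tibble(table)[, stat_cols])
  mu <- attr(table, "stat_mean")
  s <- attr(table, "stat_sd")
  degenerate <- !is.finite(s) | s == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " summary statistic(s) with zero variance dropped from distances")
  }
  keep <- stat_cols[!degenerate]
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  na_any <- colSums(is.na(z)) > 0

  obs_z <- NULL
  if (!is.null(observed)) {
    if (inherits(observed, "summary_stat_vector")) {
      observed <- as_stat_vector(observed)
    }
    if (length(observed) != length(stat_cols)) {
      stop("observed vector length does not match the reference table",
           call. = FALSE)
    }
    obs <- setNames(as.numeric(observed), stat_cols)[keep]
    obs_z <- (obs - mu[keep]) / s[keep]
    na_any <- na_any | is.na(obs_z)
  }

  ind <- NULL
  obs_ind <- NULL
  if (any(na_any)) {
    ind <- (is.na(z[, na_any, drop = FALSE])) * 1
    colnames(ind) <- paste0(colnames(z)[na_any], "_na")
    if (!is.null(obs_z)) obs_ind <- is.na(obs_z[na_any]) * 1
  }
  z[is.na(z)] <- 0
  if (!is.null(obs_z)) obs_z[is.na(obs_z)] <- 0
  list(z = cbind(z, ind),
       observed = if (is.null(obs_z)) NULL else c(obs_z, obs_ind))
}

wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, center - half), upper = min(1, center + half))
}

abc_distances <- function(observed, table) {
  st <- standardized_stats(table, observed)
  sqrt(colSums((t(st$z) - st$observed)^2))
}

#' Direct (rejection) ABC posterior probabilities
#'
#' Scenario probabilities are the scenario shares among the `n_closest`
#' reference simulations by Euclidean distance on standardized summary
#' statistics; confidence intervals are 95% Wilson binomial intervals.
#'
#' @param observed a [summary_stats()] result or the matching numeric vector
#' @param table an [build_reference_table()] result
#' @param n_closest number of retained closest simulations
#' @return an `abc_result` tibble: `scenario`, `probability`, `lower`,
#'   `upper`, with `method = "direct"` and `n_closest` attributes
#' @export
abc_direct <- function(observed, table, n_closest = 500) {
  if (n_closest < 1 || n_closest > nrow(table)) {
    stop("n_closest must lie in [1, nrow(table)]", call. = FALSE)
  }
  d <- abc_distances(observed, table)
  sel <- order(d)[seq_len(n_closest)]
  scen <- unique(table$scenario)
  counts <- table(factor(table$scenario[sel], levels = scen))
  res <- purrr::map_dfr(scen, function(sc) {
    k <- counts[[sc]]
    ci <- wilson_ci(k, n_closest)
    tibble::tibble(scenario = sc, probability = k / n_closest,
                   lower = ci["lower"], upper = ci["upper"])
  })
  structure(res, method = "direct", n_closest = n_closest,
            class = c("abc_result", class(tibble::tibble())))
}

#' Logistic-regression ABC posterior probabilities
#'
#' Multinomial logistic regression of the scenario label on the
#' standardized summary statistics centered at the observed vector, fitted
#' on the `n_retained` closest simulations; the posterior probabilities are
#' the fitted class probabilities at the observed point (the zero vector).
#' Confidence intervals propagate the intercepts' asymptotic covariance
#' through the softmax (delta method). On an ill-conditioned fit (complete
#' separation) a weight-decay (ridge) refit is used and flagged.
#'
#' @inheritParams abc_direct
#' @param n_retained number of retained closest simulations
#' @return an `abc_result` tibble: `scenario`, `probability`, `lower`,
#'   `upper`, with `method = "logistic"` attributes
#' @export
abc_logistic <- function(observed, table, n_retained = 500) {
  if (n_retained < 2 || n_retained > nrow(table)) {
    stop("n_retained must lie in [2, nrow(table)]", call. = FALSE)
  }
  st <- standardized_stats(table, observed)
  d <- sqrt(colSums((t(st$z) - st$observed)^2))
  sel <- order(d)[seq_len(n_retained)]
  scen <- unique(table$scenario)
  y <- factor(table$scenario[sel], levels = scen)
  present <- levels(droplevels(y))
  if (length(present) < 2) {
    # degenerate: every retained simulation comes from one scenario
    res <- purrr::map_dfr(scen, function(sc) {
      tibble::tibble(scenario = sc,
                     probability = as.numeric(sc == present),
                     lower = NA_real_, upper = NA_real_)
    })
    return(structure(res, method = "logistic", n_retained = n_retained,
                     ridge = FALSE,
                     class = c("abc_result", class(tibble::tibble()))))
  }
  X <- sweep(st$z[sel, , drop = FALSE], 2, st$observed)
  # drop constant columns within the retained set
  keep <- apply(X, 2, function(col) sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  y <- droplevels(y)
  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(
    nnet::multinom(y ~ ., data = dat, trace = FALSE, maxit = 500,
                   MaxNWts = 10000)
  )
  ridge <- FALSE
  if (max(abs(coef_matrix(fit))) > 30) {
    ridge <- TRUE
    fit <- suppressWarnings(
      nnet::multinom(y ~ ., data = dat, trace = FALSE, maxit = 500,
                     MaxNWts = 10000, decay = 0.1)
    )
  }
  cm <- coef_matrix(fit)
  b0 <- cm[, "(Intercept)"]
  eta <- c(0, b0)  # first present level is the baseline
  p_present <- exp(eta - max(eta))
  p_present <- p_present / sum(p_present)
  names(p_present) <- levels(y)

  se_present <- tryCatch({
    V <- vcov(fit)
    int_idx <- grep("\\(Intercept\\)$", rownames(V))
    Vb <- V[int_idx, int_idx, drop = FALSE]
    K <- length(p_present)
    se <- numeric(K)
    for (k in seq_len(K)) {
      # dp_k/db0_j for j = 2..K (baseline has no parameters)
      grad <- vapply(2:K, function(j) {
        p_present[k] * ((k == j) - p_present[j])
      }, numeric(1))
      se[k] <- sqrt(drop(t(grad) %*% Vb %*% grad))
    }
    se
  }, error = function(e) rep(NA_real_, length(p_present)))

  res <- purrr::map_dfr(scen, function(sc) {
    if (sc %in% names(p_present)) {
      k <- match(sc, names(p_present))
      p <- p_present[[k]]
      se <- se_present[k]
      tibble::tibble(scenario = sc, probability = p,
                     lower = max(0, p - 1.96 * se),
                     upper = min(1, p + 1.96 * se))
    } else {
      tibble::tibble(scenario = sc, probability = 0,
                     lower = 0, upper = 0)
    }
  })
  structure(res, method = "logistic", n_retained = n_retained, ridge = ridge,
            class = c("abc_result", class(tibble::tibble())))
}

coef_matrix <- function(fit) {
  cm <- coef(fit)
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1,
                                     dimnames = list(NULL, names(cm)))
  cm
}

#' Scenario-recovery experiment for ABC model choice
#'
#' Simulates pseudo-observed datasets under a known scenario (parameters
#' drawn from the prior), runs both model-choice estimators against a
#' reference table, and reports how often each ranks the true scenario
#' first. This is the standard calibration check that the summary
#' statistics and priors can discriminate the candidate histories.
#'
#' @param scenarios named list of candidate [scenario()]s
#' @param config a [prior_config()]
#' @param design a [sample_design()]
#' @param true_scenario name of the generating scenario
#' @param n_per_scenario reference simulations per scenario
#' @param n_pseudo number of pseudo-observed datasets
#' @param n_closest retained simulations for both estimators
#' @param seed optional integer seed
#' @return tibble with one row per pseudo-observed dataset: `true`,
#'   `best_direct`, `best_logistic`, `p_direct_true`, `p_logistic_true`,
#'   `sum_direct`, `sum_logistic`; the reference table is attached as the
#'   `reference_table` attribute
#' @export
abc_scenario_recovery <- function(scenarios, config, design, true_scenario,
                                  n_per_scenario = 3334, n_pseudo = 50,
                                  n_closest = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(true_scenario %in% names(scenarios))
  table <- build_reference_table(scenarios, config, design, n_per_scenario)
  regions <- names(design$samples)
  res <- purrr::map_dfr(seq_len(n_pseudo), function(i) {
    draw <- sample_prior(config, scenarios[[true_scenario]])
    design$mutation_rate <- draw$mu
    obs <- stat_vector_core(sim_state(draw$scenario, design), regions)
    direct <- abc_direct(obs, table, n_closest)
    logistic <- abc_logistic(obs, table, n_closest)
    tibble::tibble(
      true = true_scenario,
      best_direct = direct$scenario[which.max(direct$probability)],
      best_logistic = logistic$scenario[which.max(logistic$probability)],
      p_direct_true = direct$probability[direct$scenario == true_scenario],
      p_logistic_true = logistic$probability[logistic$scenario == true_scenario],
      sum_direct = sum(direct$probability),
      sum_logistic = sum(logistic$probability)
    )
  })
  attr(res, "reference_table") <- table
  res
}

#' Run both ABC model-choice estimators
#'
#' @inheritParams abc_direct
#' @param n_closest retained simulations for both estimators
#' @return tibble combining the [abc_direct()] and [abc_logistic()] results
#'   with a `method` column
#' @export
abc_model_choice <- function(observed, table, n_closest = 500) {
  direct <- abc_direct(observed, table, n_closest)
  logistic <- abc_logistic(observed, table, n_closest)
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(direct), method = "direct"),
    dplyr::mutate(tibble::as_tibble(logistic), method = "logistic")
  )
}
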