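#' Analysis configuration
#'
#' Bundles the tunable parameters of the scalp- and source-level analyses.
#'
#' @param csp_coverage Fraction of the total Riemannian distance the
#'   retained CSP filters must cover (default 0.90; 1.0 retains all D).
#' @param p_min,p_max Candidate VAR order range for SBC selection.
#' @param q Number of past lags in the information sub-models (default 10).
#' @param alpha Significance level of the link F-test (default 0.05).
#' @param ica_restarts Number of seeded ICA restarts (default 10).
#' @param seed Base seed for ICA initialization.
#' @param whiteness_h Maximum lag of the Li-McLeod whiteness check
#'   (default 20; must exceed the fitted order).
#' @param ftest_n Either `"n-p"` (default, effective regression sample) or
#'   `"n"` for the F-test denominator degrees of freedom.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(csp_coverage = 0.90, p_min = 1L, p_max = 10L,
                            q = 10L, alpha = 0.05, ica_restarts = 10L,
                            seed = 0L, whiteness_h = 20L,
                            ftest_n = c("n-p", "n")) {
  stopifnot(csp_coverage > 0, csp_coverage <= 1, p_min >= 1,
            p_min <= p_max, q >= 1, alpha > 0, alpha < 1,
            ica_restarts >= 1)
  structure(list(csp_coverage = csp_coverage, p_min = as.integer(p_min),
                 p_max = as.integer(p_max), q = as.integer(q),
                 alpha = alpha, ica_restarts = as.integer(ica_restarts),
                 seed = as.integer(seed),
                 whiteness_h = as.integer(whiteness_h),
                 ftest_n = match.arg(ftest_n)),
            class = "analysis_config")
}

effective_n_for <- function(config, n, p) {
  if (config$ftest_n == "n-p") n - p else n
}

trial_result_row <- function(trial, p, white, ns) {
  data.frame(trial_id = trial$trial_id, class = trial$class_label,
             order = p, whiteness_p = white,
             mean_storage = ns$mean_storage,
             mean_transfer = ns$mean_transfer,
             mean_cond_transfer = ns$mean_cond_transfer,
             n_links = ns$n_links, stringsAsFactors = FALSE)
}

#' Scalp-level information dynamics
#'
#' Runs the estimation steps directly on the (preprocessed) scalp signals,
#' bypassing spatial filtering and source separation: per trial, SBC order
#' selection, least-squares VAR fit, Li-McLeod residual whiteness check,
#' and information measures with F-tested links on the estimated
#' parameters (Q = D channels as network nodes).
#'
#' @param dataset An [eeg_dataset()].
#' @param config An [analysis_config()].
#' @return List with `summary` (one row per analyzed trial: order,
#'   whiteness p, mean storage/transfer/conditional transfer, link count)
#'   and `measures` (per-trial [information_measures()] objects, named by
#'   trial id).
#' @export
run_scalp_analysis <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  rows <- list(); meas <- list()
  for (tr in dataset$trials) {
    res <- try({
      p <- select_order(tr, config$p_min, config$p_max)$p_opt
      fit <- fit_var(tr, p)
      h <- max(config$whiteness_h, p + 1L)
      white <- licmcleod_whiteness(fit$residuals, p, h)$p_value
      im <- information_measures(
        fit$model, q = config$q,
        effective_N = effective_n_for(config, ncol(tr$data), p),
        alpha = config$alpha)
      list(p = p, white = white, im = im)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("trial '", tr$trial_id, "' skipped: ",
              attr(res, "condition")$message)
      next
    }
    meas[[tr$trial_id]] <- res$im
    rows[[tr$trial_id]] <- trial_result_row(tr, res$p, res$white,
                                            network_summary(res$im))
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       measures = meas)
}

#' Source-level information dynamics (full pipeline)
#'
#' Executes the complete two-class source analysis: (i) CSP on all trials
#' of both classes with pruning by fractional Riemannian distance;
#' (ii) per-trial VAR modeling of the reduced components at a common order
#' (the maximum of the per-trial SBC picks, so residual blocks are
#' homogeneous); (iii) Infomax ICA on the residuals concatenated over all
#' trials and classes; (iv) assembly of the overall unmixing U = W^-1 C and
#' source reconstruction; (v) per-trial similarity transform of the VAR
#' parameters to the source domain; (vi)-(vii) per-trial information
#' measures with F-tested links.
#'
#' @param dataset A two-class [eeg_dataset()] (preprocessed).
#' @param config An [analysis_config()].
#' @param C_override,W_override Optional known spatial filter matrix and
#'   mixing matrix; when supplied the corresponding estimation step (CSP,
#'   ICA) is skipped. Injecting identity matrices on a D = Q dataset makes
#'   the source analysis coincide with the scalp analysis.
#' @return List with `summary` (per-trial data frame as in
#'   [run_scalp_analysis()]), `measures` (per-trial
#'   [information_measures()]), `filterset`, `decomposition`, `unmixing`
#'   (U), `sources` (reconstructed per-trial source trials), `order`
#'   (common VAR order) and `source_models` (per-trial source-domain
#'   [var_model()]s).
#' @export
run_source_analysis <- function(dataset, config = analysis_config(),
                                C_override = NULL, W_override = NULL) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (is.null(C_override)) {
    P <- class_covariances(dataset)
    fset <- csp_filters(P[[1]], P[[2]])
    fset <- select_filters(fset, coverage = config$csp_coverage)
    C <- fset$pruned_filter
  } else {
    C <- as.matrix(C_override)
    fset <- NULL
  }
  reduced <- apply_filters(C, dataset)
  # common order: max of per-trial SBC picks, for homogeneous residuals
  orders <- vapply(reduced$trials, function(tr)
    select_order(tr, config$p_min, config$p_max)$p_opt, integer(1))
  p <- max(orders)
  fits <- lapply(reduced$trials, fit_var, p = p)
  names(fits) <- vapply(reduced$trials, `[[`, character(1), "trial_id")
  # class-1 blocks first, then class-2, trials in stored order
  ord <- order(match(vapply(reduced$trials, `[[`, character(1),
                            "class_label"), reduced$classes))
  Rall <- concatenate_residuals(lapply(fits[ord], `[[`, "residuals"))
  if (is.null(W_override)) {
    dec <- estimate_ica(Rall, n_restarts = config$ica_restarts,
                        seed = config$seed)
  } else {
    W <- as.matrix(W_override)
    dec <- structure(list(W = W, W_inv = solve(W), kurtosis = NULL,
                          restart_scores = NULL, near_gaussian = FALSE,
                          condition_number = kappa(W)),
                     class = "source_decomposition")
  }
  U <- assemble_unmixing(dec$W, C)
  sources <- lapply(dataset$trials, function(tr) reconstruct_sources(U, tr))
  rows <- list(); meas <- list(); smodels <- list()
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    fit <- fits[[tr$trial_id]]
    res <- try({
      h <- max(config$whiteness_h, p + 1L)
      white <- licmcleod_whiteness(fit$residuals, p, h)$p_value
      src <- transform_parameters(fit$model$coeffs,
                                  fit$model$innovation_cov, dec$W)
      im <- information_measures(
        src$model, q = config$q,
        effective_N = effective_n_for(config, ncol(tr$data), p),
        alpha = config$alpha)
      list(white = white, im = im, model = src$model)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("trial '", tr$trial_id, "' skipped: ",
              attr(res, "condition")$message)
      next
    }
    meas[[tr$trial_id]] <- res$im
    smodels[[tr$trial_id]] <- res$model
    rows[[tr$trial_id]] <- trial_result_row(tr, p, res$white,
                                            network_summary(res$im))
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       measures = meas, filterset = fset, decomposition = dec,
       unmixing = U, sources = sources, order = p, source_models = smodels)
}

#' Compare the two conditions on the network summary measures
#'
#' Aggregates per-trial summaries to one value per subject and condition,
#' then for each measure (mean storage, mean total transfer, mean
#' conditional transfer, link count) computes the two-sided Wilcoxon
#' rank-sum p-value, Cohen's d with its qualitative label, and the
#' percentage MAD of the trial values within each condition. P-values are
#' not corrected for multiple comparisons.
#'
#' @param summary Per-trial summary data frame from [run_scalp_analysis()]
#'   or [run_source_analysis()], with a `class` column.
#' @param subjects Optional vector assigning each row to a subject;
#'   defaults to a single subject (then tests operate on trial values and a
#'   warning is issued when a class has fewer than 2 subjects).
#' @param measures Character vector of summary columns to compare.
#' @return Data frame with one row per measure: `d`, `label`, `p_value`,
#'   `mad1`, `mad2` (percentage MAD in class 1 and class 2).
#' @export
compare_conditions <- function(summary, subjects = NULL,
                               measures = c("mean_storage", "mean_transfer",
                                            "mean_cond_transfer",
                                            "n_links")) {
  stopifnot(is.data.frame(summary), "class" %in% names(summary))
  if (is.null(subjects)) subjects <- rep("subj1", nrow(summary))
  if (length(subjects) != nrow(summary))
    stop("subjects must have one entry per summary row")
  classes <- sort(unique(summary$class))
  if (length(classes) != 2L) stop("summary must contain exactly 2 classes")
  out <- lapply(measures, function(m) {
    v <- summary[[m]]
    cl <- summary$class
    # subject-level means per class
    g1t <- v[cl == classes[1]]; g2t <- v[cl == classes[2]]
    g1 <- tapply(g1t, subjects[cl == classes[1]], mean)
    g2 <- tapply(g2t, subjects[cl == classes[2]], mean)
    # percentage MAD is undefined for a zero subject mean (e.g. a link
    # count of zero in every trial); report NA there instead of aborting
    safe_mad <- function(v, s) tryCatch(mad_percent(v, s),
                                        error = function(e) NA_real_)
    mad1 <- safe_mad(g1t, subjects[cl == classes[1]])
    mad2 <- safe_mad(g2t, subjects[cl == classes[2]])
    if (length(g1) < 2L || length(g2) < 2L) {
      warning("fewer than 2 subjects per class for '", m,
              "': descriptive output only")
      return(data.frame(measure = m, d = NA_real_, label = NA_character_,
                        p_value = NA_real_, mad1 = mad1, mad2 = mad2,
                        stringsAsFactors = FALSE))
    }
    # a degenerate measure (zero pooled SD, e.g. constant link counts)
    # has no defined effect size
    cd <- tryCatch(cohens_d(as.numeric(g1), as.numeric(g2)),
                   error = function(e) list(d = NA_real_,
                                            label = NA_character_))
    rs <- ranksum_test(as.numeric(g1), as.numeric(g2))
    data.frame(measure = m, d = cd$d, label = cd$label,
               p_value = rs$p_value, mad1 = mad1, mad2 = mad2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
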