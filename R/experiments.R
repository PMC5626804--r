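# Reproduction experiments: seeded, self-contained protocols used by the
# acceptance tests and by scripts/acceptance.R.  Each returns raw per-replicate
# measurements; summarizing and judging is left to the caller.

#' Shift-recovery experiment
#'
#' For each replicate: draw a subject, calibrate on one 40+40-trial session,
#' then evaluate on a fresh matched session and on a linearly shifted copy
#' (strength `lambda`), under the static protocol, the adaptive protocol with
#' the given buffer, and at the extra sweep sizes.  Evaluation sessions hold
#' `n_eval_per_class` trials per class (200 trials by default, mirroring the
#' multi-run evaluation days the protocol models); all arms score the same
#' post-buffer trials.
#'
#' @param n_reps replicates (independent subjects).
#' @param lambda between-session shift strength.
#' @param seed master seed; every replicate derives its seeds from it.
#' @param n_calib_per_class,n_eval_per_class trials per class.
#' @param buffer_size adaptation buffer for the main adaptive arm.
#' @param sweep_sizes additional buffer sizes evaluated on the shifted
#'   session (scored past `max(sweep_sizes, buffer_size)` trials).
#' @return data.frame with one row per replicate: `ceiling` (static accuracy
#'   on the matched session), `static`, `adaptive` (shifted session),
#'   `adaptive_matched`, and one `sweep_<k>` column per sweep size.
#' @export
shift_recovery_experiment <- function(n_reps = 20L, lambda = 0.4, seed = 1L,
                                      n_calib_per_class = 40L,
                                      n_eval_per_class = 100L,
                                      buffer_size = 20L,
                                      sweep_sizes = c(2L, 20L)) {
  skip <- max(c(buffer_size, sweep_sizes))
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    base <- seed * 1009L + r * 13L
    spec_c <- synth_spec(n_trials_per_class = n_calib_per_class, seed = base)
    spec_e <- synth_spec(n_trials_per_class = n_eval_per_class, seed = base)
    model <- calibrate(generate_session(spec_c, session_seed = base + 1L))
    eval0 <- generate_session(spec_e, session_seed = base + 2L)
    evalS <- apply_session_shift(eval0, lambda, seed = base + 3L)
    be0 <- prepare_eval(model, eval0)
    beS <- prepare_eval(model, evalS)
    row <- c(ceiling = evaluate_static(model, be0, skip_first = skip)$accuracy_pct,
             static = evaluate_static(model, beS, skip_first = skip)$accuracy_pct,
             adaptive = evaluate_adaptive(model, beS, buffer_size,
                                          skip_first = skip)$accuracy_pct,
             adaptive_matched = evaluate_adaptive(model, be0, buffer_size,
                                                  skip_first = skip)$accuracy_pct)
    for (k in sweep_sizes) {
      if (k == buffer_size) {
        row[paste0("sweep_", k)] <- row[["adaptive"]]
      } else {
        row[paste0("sweep_", k)] <-
          evaluate_adaptive(model, beS, k, skip_first = skip)$accuracy_pct
      }
    }
    out[[r]] <- row
  }
  as.data.frame(do.call(rbind, out))
}

#' Null screening experiment
#'
#' Generates label-shuffled sessions (the null world) and records the
#' 10 x 10-fold cross-validation mean accuracy of each.
#'
#' @param n_seeds sessions to screen.
#' @param seed master seed.
#' @return numeric vector of mean CV accuracies (percent).
#' @export
null_screen_experiment <- function(n_seeds = 20L, seed = 1L) {
  vapply(seq_len(n_seeds), function(r) {
    base <- seed * 2003L + r * 17L
    es <- generate_session(synth_spec(seed = base), session_seed = base + 1L)
    es$labels <- withr::with_seed(base + 2L, sample(es$labels))
    crossval_screen(es, pipeline_config(seed = base + 3L))$mean_accuracy_pct
  }, 0)
}

#' Closed-form-versus-numerical-minimizer experiment
#'
#' For random SPD quadruples (dimension 2-5), measures (a) the gap between
#' the adaptation loss attained by the closed-form transform and a BFGS
#' minimizer started from it, and (b) how many random perturbations
#' `V* + delta` (`||delta||_F = perturb_scale`) attain a strictly smaller
#' loss.  Instances on which the closed form has no real principal square
#' root (possible for strongly mismatched inputs) are recorded as `NA`.
#'
#' @param n_instances random instances.
#' @param n_perturb perturbations per instance.
#' @param perturb_scale Frobenius norm of each perturbation.
#' @param seed master seed.
#' @return data.frame: `n`, `loss_closed_form`, `loss_bfgs`, `gap`,
#'   `n_perturb_better`.
#' @export
closed_form_optimality_experiment <- function(n_instances = 100L,
                                              n_perturb = 1e4L,
                                              perturb_scale = 0.01,
                                              seed = 1L) {
  withr::with_seed(seed, {
    out <- vector("list", n_instances)
    for (i in seq_len(n_instances)) {
      n <- sample(2:5, 1)
      ev <- class_covariances_obj(rspd_internal(n), rspd_internal(n))
      calib <- class_covariances_obj(rspd_internal(n), rspd_internal(n))
      V <- tryCatch(solve_transform(ev, calib), error = function(e) NULL)
      if (is.null(V)) {
        out[[i]] <- data.frame(n = n, loss_closed_form = NA_real_,
                               loss_bfgs = NA_real_, gap = NA_real_,
                               n_perturb_better = NA_integer_)
        next
      }
      f <- function(v) {
        M <- matrix(v, n)
        if (abs(det(M)) < 1e-12) return(1e10)
        tryCatch(adaptation_loss(M, ev, calib), error = function(e) 1e10)
      }
      l0 <- f(as.vector(V))
      opt <- stats::optim(as.vector(V), f, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-14))
      deltas <- matrix(stats::rnorm(n_perturb * n * n), n_perturb)
      deltas <- deltas / sqrt(rowSums(deltas^2)) * perturb_scale
      better <- sum(apply(deltas, 1, function(d) f(as.vector(V) + d) < l0))
      out[[i]] <- data.frame(n = n, loss_closed_form = l0,
                             loss_bfgs = opt$value, gap = l0 - opt$value,
                             n_perturb_better = better)
    }
    do.call(rbind, out)
  })
}

# internal random SPD helper for the experiment above
rspd_internal <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) + diag(0.1, n)
}

#' Monte-Carlo validation of the Gaussian KL divergence
#'
#' Draws random SPD pairs (dimension 2-3) and compares [gaussian_kl()] with a
#' Monte-Carlo estimate from `n_samples` draws.
#'
#' @param n_instances pairs tested.
#' @param n_samples Monte-Carlo sample size per pair.
#' @param seed master seed.
#' @return data.frame: `d`, `analytic`, `mc`, `se`, `abs_z` (absolute
#'   discrepancy in standard errors).
#' @export
kl_monte_carlo_experiment <- function(n_instances = 20L, n_samples = 1e6,
                                      seed = 1L) {
  withr::with_seed(seed, {
    out <- vector("list", n_instances)
    for (i in seq_len(n_instances)) {
      d <- sample(2:3, 1)
      S <- rspd_internal(d)
      R <- rspd_internal(d)
      analytic <- gaussian_kl(S, R)
      logq <- function(X, C) {
        L <- chol(C)
        w <- forwardsolve(t(L), t(X))
        -0.5 * colSums(w^2) - sum(log(diag(L))) - d / 2 * log(2 * pi)
      }
      # chunked to bound memory
      tot <- 0; tot2 <- 0; m <- 0
      while (m < n_samples) {
        k <- min(2e5, n_samples - m)
        Z <- matrix(stats::rnorm(k * d), k) %*% chol(S)
        v <- logq(Z, S) - logq(Z, R)
        tot <- tot + sum(v); tot2 <- tot2 + sum(v^2); m <- m + k
      }
      mc <- tot / m
      se <- sqrt((tot2 / m - mc^2) / m)
      out[[i]] <- data.frame(d = d, analytic = analytic, mc = mc, se = se,
                             abs_z = abs(analytic - mc) / se)
    }
    do.call(rbind, out)
  })
}
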