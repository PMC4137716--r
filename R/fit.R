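#' Model variants of the Kronecker codon family
#'
#' Defines a member of the model family and its free-parameter accounting:
#'
#' * `M0` - single-hit baseline, parameters kappa and omega (k = 2);
#' * `KCM7x` - one shared positional matrix Kronecker-cubed, multi-hit
#'   substitutions allowed (6 rates + omega, k = 7);
#' * `KCM7xM0` - as KCM7x with the multi-hit switch alpha = 0 (k = 7);
#' * `KCM19x` - three distinct positional matrices, multi-hit allowed
#'   (18 rates + omega, k = 19);
#' * `KCM19xM0` - as KCM19x with alpha = 0 (k = 19);
#' * `KCM19x_neutral` - as KCM19x with omega fixed to 1 (k = 18).
#'
#' Codon-frequency parameters are excluded from `k_free`: within a given
#' frequency mode they add the same count to every model compared, so they
#' cancel from AICc differences.
#'
#' @param name model name (see above).
#' @param freq_mode codon frequency scheme used when fitting.
#' @return a `model_spec` list: `name`, `alpha`, `tie_positions`,
#'   `omega_fixed`, `freq_mode`, `k_free`.
#' @export
model_spec <- function(name = c("M0", "KCM7x", "KCM7xM0", "KCM19x",
                                "KCM19xM0", "KCM19x_neutral"),
                       freq_mode = c("F3X4", "F61", "EQUAL")) {
  name <- match.arg(name)
  freq_mode <- match.arg(freq_mode)
  tab <- list(
    M0             = list(alpha = 0, tie = NA,    omega_fixed = NULL, k = 2L),
    KCM7x          = list(alpha = 1, tie = TRUE,  omega_fixed = NULL, k = 7L),
    KCM7xM0        = list(alpha = 0, tie = TRUE,  omega_fixed = NULL, k = 7L),
    KCM19x         = list(alpha = 1, tie = FALSE, omega_fixed = NULL, k = 19L),
    KCM19xM0       = list(alpha = 0, tie = FALSE, omega_fixed = NULL, k = 19L),
    KCM19x_neutral = list(alpha = 1, tie = FALSE, omega_fixed = 1,    k = 18L))
  v <- tab[[name]]
  structure(list(name = name, alpha = v$alpha, tie_positions = v$tie,
                 omega_fixed = v$omega_fixed, freq_mode = freq_mode,
                 k_free = v$k),
            class = "model_spec")
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1).  The sample size n is the
#' number of codon columns, the independent sampling units of the
#' likelihood.
#'
#' @param lnL maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size; must exceed k + 1.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc difference between a reference and an alternative fit
#'
#' Returns AICc(reference) - AICc(alternative); positive values favor the
#' alternative model.  Conventionally the reference is M0 and the
#' alternative a multi-hit variant.
#'
#' @param fit_ref,fit_alt `kcm_fit` objects on the same alignment and tree.
#' @export
delta_aicc <- function(fit_ref, fit_alt) {
  if (fit_ref$n_sites != fit_alt$n_sites ||
      !identical(sort(fit_ref$taxa), sort(fit_alt$taxa)))
    stop("fits are not on the same alignment")
  fit_ref$aicc - fit_alt$aicc
}

# -- parameter packing --------------------------------------------------------

RATE_LO <- log(1e-8); RATE_HI <- log(1e3)
OMEGA_LO <- log(1e-6); OMEGA_HI <- log(1e3)
BL_LO <- log(1e-8); BL_HI <- log(1e3)

pack_layout <- function(spec, n_edge, optimize_bl) {
  n_rates <- if (spec$name == "M0") 1L else if (spec$tie_positions) 6L else 18L
  n_omega <- if (is.null(spec$omega_fixed)) 1L else 0L
  n_bl <- if (optimize_bl) n_edge else 0L
  idx <- list(rates = seq_len(n_rates),
              omega = if (n_omega) n_rates + 1L else integer(),
              bl = if (n_bl) n_rates + n_omega + seq_len(n_bl) else integer())
  lower <- c(rep(RATE_LO, n_rates), rep(OMEGA_LO, n_omega), rep(BL_LO, n_bl))
  upper <- c(rep(RATE_HI, n_rates), rep(OMEGA_HI, n_omega), rep(BL_HI, n_bl))
  list(idx = idx, lower = lower, upper = upper,
       n_par = n_rates + n_omega + n_bl)
}

# build the generator for a parameter vector (natural scale pieces)
spec_generator <- function(spec, rates, omega, freqs, code) {
  if (spec$name == "M0")
    return(build_m0_Q(rates[1], omega, freqs, code))
  if (spec$tie_positions) {
    q <- nuc_exchange_matrix(rates)
    build_kcm_Q(q, q, q, freqs, omega, spec$alpha, code)
  } else {
    q1 <- nuc_exchange_matrix(rates[1:6], 1L)
    q2 <- nuc_exchange_matrix(rates[7:12], 2L)
    q3 <- nuc_exchange_matrix(rates[13:18], 3L)
    build_kcm_Q(q1, q2, q3, freqs, omega, spec$alpha, code)
  }
}

default_start <- function(spec, tree_bl, optimize_bl) {
  n_rates <- if (spec$name == "M0") 1L else if (spec$tie_positions) 6L else 18L
  start_rates <- if (spec$name == "M0") log(2) else rep(0, n_rates)
  c(start_rates,
    if (is.null(spec$omega_fixed)) 0,       # omega = 1
    if (optimize_bl) log(pmax(tree_bl, 1e-6)))
}

#' Maximum-likelihood fit of a codon model
#'
#' Maximizes the log-likelihood over the model's free rate parameters,
#' omega (unless fixed by the variant), and optionally the branch lengths,
#' all log-transformed, with bounded quasi-Newton (L-BFGS-B).  Several
#' starting points are tried (the unit-rate start plus random lognormal
#' perturbations, plus any user-supplied starts) and the best kept.
#' Non-convergence is reported through `converged = FALSE`, never as an
#' error.
#'
#' @param aln a [codon_alignment()].
#' @param tree an [ape::phylo] tree with starting branch lengths.
#' @param spec a [model_spec()] or model name.
#' @param freqs optional [codon_frequencies()]; default estimated from the
#'   alignment under `spec$freq_mode`.
#' @param optimize_branch_lengths jointly optimize branch lengths
#'   (default `TRUE`; with `FALSE` the input lengths are held fixed).
#' @param n_starts number of starting points (default 3: unit rates plus
#'   two seeded lognormal perturbations, sd 0.3 on the log scale).
#' @param init optional list (or list of lists) of extra warm starts with
#'   elements `rates`, `omega`, `branch_lengths` (natural scale; missing
#'   pieces fall back to the default start).
#' @param seed integer seed controlling the random starts; `NULL` leaves the
#'   RNG state alone.
#' @param control passed to [stats::optim()] (defaults
#'   `maxit = 300, factr = 1e8`).
#' @param code genetic code object.
#' @return a `kcm_fit`: `spec`, `lnL`, `params` (named rates and
#'   omega/kappa), `Q`, `tree` (with fitted branch lengths), `aicc`,
#'   `n_sites`, `k`, `converged`, `n_evals`, `seed`, `freqs`, `taxa`.
#' @export
fit_codon_model <- function(aln, tree, spec = "M0", freqs = NULL,
                            optimize_branch_lengths = TRUE, n_starts = 3L,
                            init = NULL, seed = NULL, control = list(),
                            code = NULL) {
  code <- get_code(code)
  if (is.character(spec)) spec <- model_spec(spec)
  if (is.null(freqs)) freqs <- estimate_frequencies(aln, spec$freq_mode, code)
  if (!is.null(seed)) set.seed(seed)

  prep <- prep_tree(tree, aln$taxa)
  cp <- compress_patterns(aln$states[prep$tip_order, , drop = FALSE])
  layout <- pack_layout(spec, length(prep$edge_len), optimize_branch_lengths)
  idx <- layout$idx
  n_evals <- 0L

  build_Q <- function(par) {
    rates <- exp(par[idx$rates])
    omega <- if (length(idx$omega)) exp(par[idx$omega]) else spec$omega_fixed
    tryCatch(spec_generator(spec, rates, omega, freqs, code),
             error = function(e) NULL)
  }
  edge_lengths <- function(par)
    if (length(idx$bl)) exp(par[idx$bl]) else prep$edge_len

  objective <- function(par) {
    n_evals <<- n_evals + 1L
    Q <- build_Q(par)
    if (is.null(Q)) return(1e10)
    ll <- cpp_loglik(Q$Q, Q$pi, prep$edge, edge_lengths(par), cp$pat, cp$w,
                     prep$n_node)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # gradient: analytic in the branch lengths (pruning with an extra
  # pre-order pass), forward finite differences in the few rate/omega
  # coordinates
  gradient <- function(par) {
    g <- numeric(length(par))
    fd_cols <- c(idx$rates, idx$omega)
    Q <- build_Q(par)
    f0 <- NA_real_
    if (!is.null(Q) && length(idx$bl)) {
      res <- cpp_loglik_grad(Q$Q, Q$pi, prep$edge, edge_lengths(par),
                             cp$pat, cp$w, prep$n_node)
      if (is.finite(res$loglik)) {
        f0 <- -res$loglik
        g[idx$bl] <- -res$grad * exp(par[idx$bl])  # chain rule for log-scale
      } else {
        fd_cols <- c(fd_cols, idx$bl)
      }
    } else if (length(idx$bl)) {
      fd_cols <- c(fd_cols, idx$bl)
    }
    if (is.na(f0)) f0 <- objective(par)
    h <- 1e-6
    for (i in fd_cols) {
      pp <- par
      pp[i] <- pp[i] + h
      g[i] <- (objective(pp) - f0) / h
    }
    g
  }

  base <- default_start(spec, prep$edge_len, optimize_branch_lengths)
  starts <- list(base)
  if (n_starts > 1L) {
    for (s in seq_len(n_starts - 1L))
      starts[[length(starts) + 1L]] <-
        pmin(pmax(base + stats::rnorm(length(base), 0, 0.3)),
             layout$upper - 1e-6)
  }
  if (!is.null(init)) {
    if (!is.null(names(init))) init <- list(init)
    for (ini in init) {
      v <- base
      if (!is.null(ini$rates)) v[idx$rates] <- log(pmax(ini$rates, 1.1e-8))
      if (!is.null(ini$omega) && length(idx$omega)) v[idx$omega] <- log(ini$omega)
      if (!is.null(ini$branch_lengths) && length(idx$bl))
        v[idx$bl] <- log(pmax(ini$branch_lengths, 1.1e-8))
      starts[[length(starts) + 1L]] <- v
    }
  }
  starts <- lapply(starts, function(v) pmin(pmax(v, layout$lower), layout$upper))

  ctrl <- utils::modifyList(list(maxit = 300, factr = 1e8), control)
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, objective, gradient, method = "L-BFGS-B",
                   lower = layout$lower, upper = layout$upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimization starts failed")
  converged <- best$convergence == 0
  if (!converged)
    warning("optimizer did not report convergence (code ", best$convergence,
            "): ", best$message)

  par <- best$par
  rates <- exp(par[idx$rates])
  omega <- if (length(idx$omega)) exp(par[idx$omega]) else spec$omega_fixed
  Q <- spec_generator(spec, rates, omega, freqs, code)
  fitted_tree <- tree
  if (length(idx$bl)) {
    tree_post <- ape::reorder.phylo(tree, "postorder")
    tree_post$edge.length <- exp(par[idx$bl])
    fitted_tree <- tree_post
  }
  pair_names <- c("TC", "TA", "TG", "CA", "CG", "AG")
  params <- if (spec$name == "M0") {
    c(kappa = unname(rates[1]), omega = omega)
  } else {
    nm <- if (spec$tie_positions) pair_names
          else paste0("q", rep(1:3, each = 6), ".", rep(pair_names, 3))
    c(stats::setNames(rates, nm),
      if (is.null(spec$omega_fixed)) c(omega = omega))
  }
  lnL <- -best$value
  structure(list(spec = spec, lnL = lnL, params = params,
                 omega = omega, rates = rates, Q = Q, tree = fitted_tree,
                 branch_lengths = fitted_tree$edge.length,
                 aicc = aicc(lnL, spec$k_free, aln$n_sites),
                 n_sites = aln$n_sites, k = spec$k_free, taxa = aln$taxa,
                 freqs = freqs, converged = converged, n_evals = n_evals,
                 seed = seed),
            class = "kcm_fit")
}

#' @export
print.kcm_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, n = %d codon sites, AICc = %.4f\n",
              x$spec$name, x$lnL, x$k, x$n_sites, x$aicc))
  if (!is.null(x$omega)) cat(sprintf("  omega = %.4f\n", x$omega))
  if (!x$converged) cat("  (optimizer did not report convergence)\n")
  invisible(x)
}

#' Fit several models to one data set and compare by AICc
#'
#' @param aln,tree data as in [fit_codon_model()].
#' @param models character vector of model names.
#' @param ... passed to [fit_codon_model()].
#' @return list with `fits` (named list of `kcm_fit`) and `table`
#'   (data.frame with lnL, k, AICc, delta AICc vs the first model).
#' @export
compare_models <- function(aln, tree, models = c("M0", "KCM7x", "KCM19x"), ...) {
  fits <- lapply(models, function(m) fit_codon_model(aln, tree, m, ...))
  names(fits) <- models
  tab <- data.frame(
    model = models,
    lnL = vapply(fits, `[[`, 0, "lnL"),
    k = vapply(fits, `[[`, 0L, "k"),
    AICc = vapply(fits, `[[`, 0, "aicc"),
    omega = vapply(fits, function(f) if (is.null(f$omega)) NA_real_ else f$omega, 0),
    row.names = NULL)
  tab$delta_AICc_vs_first <- tab$AICc[1] - tab$AICc
  list(fits = fits, table = tab)
}

#' Replicated simulation-and-refit study
#'
#' The machine analog of a simulation table: for each replicate, draw a
#' random tree, build the scheme's generator, simulate an alignment, fit
#' every requested model, and record omega (raw and, for multi-hit KCM
#' variants, flux-corrected), log-likelihood, AICc, and the AICc difference
#' to M0.  Fully reproducible from `seed`.
#'
#' @param scheme scheme name (`"A"`, `"B"`, `"C"`, `"D"`, `"EXTERNAL"`) or a
#'   [simulation_scheme()] object.
#' @param factor multiplier applied to every nonsynonymous rate of the
#'   generating matrix (the true omega of scheme A).
#' @param n_reps number of replicates.
#' @param n_taxa,n_codons dimensions of each simulated data set.
#' @param models character vector of models to fit.
#' @param freq_mode frequency scheme used for fitting.
#' @param seed integer seed for the whole study.
#' @param n_starts starting points per fit (default 1; each multi-hit KCM
#'   fit additionally warm-starts from the replicate's M0 solution when
#'   available).
#' @param bl_mean,bl_sd branch-length mean and SD of the random trees
#'   (see [random_tree()]).
#' @param log_params interpret `bl_mean`/`bl_sd` on the log scale.
#' @param control optimizer control, passed on.
#' @return list with `replicates` (long data.frame, one row per replicate x
#'   model) and `summary` (per model: mean/sd of omega, corrected omega, and
#'   delta AICc vs M0), plus the study configuration.
#' @export
replicate_study <- function(scheme, factor = 1, n_reps = 50L, n_taxa = 15L,
                            n_codons = 150L,
                            models = c("M0", "KCM19x"),
                            freq_mode = "F3X4", seed = 1L, n_starts = 1L,
                            bl_mean = 0.41, bl_sd = 0.34, log_params = FALSE,
                            control = list(), code = NULL) {
  code <- get_code(code)
  if (is.character(scheme)) scheme <- simulation_scheme(scheme)
  set.seed(seed)
  rows <- list()
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      tree <- random_tree(n_taxa, bl_mean, bl_sd, log_params)
      Qgen <- build_scheme_matrix(scheme, omega_factor = factor, code = code)
      aln <- simulate_alignment(tree, Qgen, n_codons)
      freqs <- estimate_frequencies(aln, freq_mode, code)
      m0_fit <- NULL
      rep_rows <- list()
      ord <- unique(c(intersect("M0", models), models))
      for (m in ord) {
        init <- NULL
        sp <- model_spec(m, freq_mode)
        if (!is.null(m0_fit) && m != "M0") {
          # warm start at the M0 solution: transition/transversion pattern,
          # damped so multi-hit flux starts small for alpha = 1 variants
          damp <- if (sp$alpha == 1) 0.3 else 1
          r6 <- c(TC = m0_fit$params[["kappa"]], TA = 1, TG = 1,
                  CA = 1, CG = 1, AG = m0_fit$params[["kappa"]]) * damp
          init <- list(rates = if (isTRUE(sp$tie_positions)) r6 else rep(r6, 3),
                       omega = m0_fit$omega,
                       branch_lengths = m0_fit$branch_lengths)
        }
        f <- fit_codon_model(aln, tree, sp, freqs = freqs,
                             n_starts = n_starts, init = init,
                             control = control, code = code)
        if (m == "M0") m0_fit <- f
        om_c <- NA_real_
        if (m != "M0") {
          om_c <- tryCatch(corrected_omega(f, code)$omega_kcm,
                           error = function(e) NA_real_)
        }
        rep_rows[[m]] <- data.frame(
          replicate = r, model = m, lnL = f$lnL, k = f$k, aicc = f$aicc,
          omega = if (is.null(f$omega)) NA_real_ else f$omega,
          omega_corrected = om_c, converged = f$converged,
          multi_hit_frac_gen = multi_hit_fraction(Qgen, code))
      }
      if (!is.null(m0_fit))
        for (m in names(rep_rows))
          rep_rows[[m]]$delta_aicc_vs_M0 <- m0_fit$aicc - rep_rows[[m]]$aicc
      do.call(rbind, rep_rows)
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_fail <- n_fail + 1L else rows[[length(rows) + 1L]] <- res
  }
  if (n_fail > 0.2 * n_reps)
    stop("more than 20% of replicates failed (", n_fail, "/", n_reps, ")")
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  summ <- do.call(rbind, lapply(split(reps, reps$model), function(d) {
    data.frame(model = d$model[1], n = nrow(d),
               omega_mean = agg(d$omega)[1], omega_sd = agg(d$omega)[2],
               omega_corr_mean = agg(d$omega_corrected)[1],
               omega_corr_sd = agg(d$omega_corrected)[2],
               delta_aicc_mean = agg(d$delta_aicc_vs_M0)[1],
               delta_aicc_sd = agg(d$delta_aicc_vs_M0)[2])
  }))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ, n_failed = n_fail,
       config = list(scheme = scheme$name, factor = factor, n_reps = n_reps,
                     n_taxa = n_taxa, n_codons = n_codons, models = models,
                     freq_mode = freq_mode, seed = seed, n_starts = n_starts,
                     bl_mean = bl_mean, bl_sd = bl_sd, log_params = log_params))
}
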