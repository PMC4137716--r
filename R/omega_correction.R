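#' Synonymous or nonsynonymous substitution flux of a generator
#'
#' The expected substitution rate per codon restricted to one class of
#' change: the sum of pi_i Q_ij over ordered pairs i != j whose codons
#' encode the same amino acid (`synonymous = TRUE`) or different amino
#' acids (`FALSE`).  For a unit-scaled generator the two fluxes sum to 1.
#'
#' @param Q a `codon_rate_matrix`.
#' @param synonymous which flux to report.
#' @param code genetic code object.
#' @export
substitution_flux <- function(Q, synonymous = TRUE, code = NULL) {
  code <- get_code(code)
  M <- Q$Q
  diag(M) <- 0
  mask <- if (synonymous) code$synonymous else !code$synonymous
  sum((Q$pi * M)[mask])
}

#' Flux-corrected omega for multi-hit positional models
#'
#' When the three codon positions carry different nucleotide rates and
#' double/triple substitutions are allowed, the raw omega multiplier of the
#' generator no longer equals the dN/dS ratio measured against a neutral
#' expectation.  The correction divides the model's nonsynonymous-to-
#' synonymous flux ratio by the same ratio under a neutral reference:
#' omega = 1 and one common positional matrix, obtained by averaging the
#' three fitted nucleotide matrices entrywise.  The reference keeps the
#' fitted codon frequencies and multi-hit switch, and is rescaled to unit
#' mean rate (the ratio form makes the scaling immaterial).
#'
#' omega_corrected = (rho_a / rho_s) / (rho_a_neutral / rho_s_neutral),
#' the number of nonsynonymous substitutions per nonsynonymous site over
#' the number of synonymous substitutions per synonymous site.
#'
#' @param fit a `kcm_fit` for a KCM variant (not M0), or a list with
#'   elements `rates` (6 or 18 values), `omega`, `spec` (for `alpha` and
#'   `tie_positions`) and `freqs`.
#' @param code genetic code object.
#' @return list of class `flux_summary`: `rho_s`, `rho_a`, `rho_s_inf`,
#'   `rho_a_inf`, `omega_raw`, `omega_kcm`.
#' @export
corrected_omega <- function(fit, code = NULL) {
  code <- get_code(code)
  if (fit$spec$name == "M0")
    stop("corrected omega is defined for KCM variants, not M0")
  rates <- fit$rates
  if (isTRUE(fit$spec$tie_positions)) rates <- rep(rates, 3)
  q1 <- nuc_exchange_matrix(rates[1:6], 1L)
  q2 <- nuc_exchange_matrix(rates[7:12], 2L)
  q3 <- nuc_exchange_matrix(rates[13:18], 3L)
  omega <- if (is.null(fit$omega)) 1 else fit$omega
  Q <- build_kcm_Q(q1, q2, q3, fit$freqs, omega, fit$spec$alpha, code)
  rho_s <- substitution_flux(Q, TRUE, code)
  rho_a <- substitution_flux(Q, FALSE, code)
  if (rho_s <= 0) stop("degenerate model: zero synonymous flux")

  qbar <- nuc_exchange_matrix((attr(q1, "rates") + attr(q2, "rates") +
                                 attr(q3, "rates")) / 3)
  Qinf <- build_kcm_Q(qbar, qbar, qbar, fit$freqs, omega = 1,
                      alpha = fit$spec$alpha, code = code)
  rho_s_inf <- substitution_flux(Qinf, TRUE, code)
  rho_a_inf <- substitution_flux(Qinf, FALSE, code)
  if (rho_a_inf <= 0 || rho_s_inf <= 0)
    stop("degenerate neutral reference: zero flux")

  structure(list(rho_s = rho_s, rho_a = rho_a,
                 rho_s_inf = rho_s_inf, rho_a_inf = rho_a_inf,
                 omega_raw = omega,
                 omega_kcm = (rho_a / rho_s) / (rho_a_inf / rho_s_inf)),
            class = "flux_summary")
}

#' @export
print.flux_summary <- function(x, ...) {
  cat(sprintf("fluxes per codon: synonymous %.5f, nonsynonymous %.5f\n",
              x$rho_s, x$rho_a))
  cat(sprintf("neutral reference: synonymous %.5f, nonsynonymous %.5f\n",
              x$rho_s_inf, x$rho_a_inf))
  cat(sprintf("omega: raw %.4f, corrected %.4f\n", x$omega_raw, x$omega_kcm))
  invisible(x)
}
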