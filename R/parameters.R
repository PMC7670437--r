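# Universal constants of the two segment-activity-coefficient model
# generations.  These are configuration, not ground truth: the defaults
# follow the parameter sets published with the public sigma-profile
# database (2002 generation) and with the temperature-dependent revision
# (2010 generation), and every value can be overridden.

#' Parameters of the original (2002) segment activity coefficient model
#'
#' @param a_eff effective segment area (A^2).
#' @param alpha_prime misfit energy constant (kcal A^4 / (mol e^2)).
#' @param c_hb hydrogen-bonding energy constant (kcal A^4 / (mol e^2)).
#' @param sigma_hb hydrogen-bonding cutoff (e/A^2).
#' @param q0 normalization surface area (A^2).
#' @param r0 normalization volume (A^3).
#' @param z lattice coordination number of the combinatorial term.
#' @param R gas constant in kcal/(mol K), consistent with `alpha_prime`.
#' @return list of class `cosmosac2002_params`.
#' @export
cosmosac2002_params <- function(a_eff = 7.50, alpha_prime = 16466.72,
                                c_hb = 85580.0, sigma_hb = 0.0084,
                                q0 = 79.53, r0 = 66.69, z = 10,
                                R = 0.001987) {
  p <- list(a_eff = a_eff, alpha_prime = alpha_prime, c_hb = c_hb,
            sigma_hb = sigma_hb, q0 = q0, r0 = r0, z = z, R = R)
  if (any(unlist(p) <= 0)) stop("all 2002 model parameters must be strictly positive")
  structure(p, class = "cosmosac2002_params")
}

#' Parameters of the revised (2010) segment activity coefficient model
#'
#' The electrostatic constant is temperature dependent,
#' \eqn{A_{ES} + B_{ES}/T^2}, and hydrogen bonding uses class-pair specific
#' constants on the NHB/OH/OT split of the sigma profile.  `hb_sign = -1`
#' (the default) makes the hydrogen-bond term attractive, as in the model's
#' source publication; `+1` gives the literal repulsive form some
#' transcriptions print.
#'
#' @param A_ES electrostatic constant (kcal A^4 / (mol e^2)).
#' @param B_ES temperature coefficient (kcal A^4 K^2 / (mol e^2)).
#' @param c_OH_OH,c_OT_OT,c_OH_OT hydrogen-bonding constants per class pair.
#' @param sigma0 hydrogen-bonding threshold of the profile split (e/A^2).
#' @param hb_sign sign of the hydrogen-bond term, `-1` or `+1`.
#' @param a_eff,q0,r0,z,R shared constants as in [cosmosac2002_params()].
#' @return list of class `cosmosac2010_params`.
#' @export
cosmosac2010_params <- function(A_ES = 6525.69, B_ES = 1.4859e8,
                                c_OH_OH = 4013.78, c_OT_OT = 932.31,
                                c_OH_OT = 3016.43, sigma0 = 0.007,
                                hb_sign = -1, a_eff = 7.50,
                                q0 = 79.53, r0 = 66.69, z = 10,
                                R = 0.001987) {
  if (!hb_sign %in% c(-1, 1)) stop("hb_sign must be -1 or +1")
  p <- list(A_ES = A_ES, B_ES = B_ES, c_OH_OH = c_OH_OH, c_OT_OT = c_OT_OT,
            c_OH_OT = c_OH_OT, sigma0 = sigma0, hb_sign = hb_sign,
            a_eff = a_eff, q0 = q0, r0 = r0, z = z, R = R)
  must_pos <- c("A_ES", "c_OH_OH", "c_OT_OT", "c_OH_OT", "sigma0",
                "a_eff", "q0", "r0", "z", "R")
  if (any(unlist(p[must_pos]) <= 0) || B_ES < 0) {
    stop("2010 model parameters must be positive (B_ES may be zero)")
  }
  structure(p, class = "cosmosac2010_params")
}
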