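# Sexual development and Y-chromosomal fitness effects -----------------------

#' Sex-determination parameters
#'
#' Threshold model of sexual development. The summed net expression of an
#' individual's two F alleles is compared with two thresholds: above
#' `theta_f` the individual develops as female, below `theta_m` as male,
#' and in between as an infertile intersex. `beta` is the linear rate at
#' which normalized temperature raises F expression, and `sigma_eps` the
#' standard deviation of the per-allele Gaussian expression noise.
#'
#' @param theta_f Feminization threshold (expression units).
#' @param theta_m Masculinization threshold; must satisfy
#'   `theta_m < theta_f`.
#' @param beta Temperature slope of F expression, >= 0.
#' @param sigma_eps Standard deviation of expression noise, >= 0.
#' @return A list of class `"gsd_development_params"`.
#' @export
development_params <- function(theta_f = 1.2, theta_m = 0.2,
                               beta = 0, sigma_eps = 0.05) {
  if (!is.finite(theta_f) || !is.finite(theta_m) || theta_m >= theta_f) {
    stop("thresholds must satisfy theta_m < theta_f")
  }
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0")
  if (!is.finite(sigma_eps) || sigma_eps < 0) stop("sigma_eps must be >= 0")
  structure(list(theta_f = theta_f, theta_m = theta_m,
                 beta = beta, sigma_eps = sigma_eps),
            class = "gsd_development_params")
}

#' Y-chromosomal fitness parameters
#'
#' `s_yy` multiplies the survival of individuals homozygous for the
#' Y-chromosome. `s_a` is the sexually antagonistic effect of Y-linked
#' variation: Y-bearing males have fitness multiplied by `1 + s_a`,
#' Y-bearing females by `1 - s_a`; the two effects combine
#' multiplicatively, so a YY male gets `s_yy * (1 + s_a)` and a YY female
#' `s_yy * (1 - s_a)`.
#'
#' @param s_yy Viability multiplier of YY homozygotes, in \[0, 1\].
#' @param s_a Sexually antagonistic Y effect, >= 0.
#' @param sa_on_mating If `TRUE`, the sexually antagonistic factor acts as
#'   a mating-success weight at reproduction instead of a survival
#'   probability at development (the YY viability factor always acts on
#'   survival). Default `FALSE`.
#' @return A list of class `"gsd_fitness_params"`.
#' @export
fitness_params <- function(s_yy = 1, s_a = 0, sa_on_mating = FALSE) {
  if (!is.finite(s_yy) || s_yy < 0 || s_yy > 1) stop("s_yy must be in [0, 1]")
  if (!is.finite(s_a) || s_a < 0) stop("s_a must be >= 0")
  structure(list(s_yy = s_yy, s_a = s_a,
                 sa_on_mating = isTRUE(sa_on_mating)),
            class = "gsd_fitness_params")
}

#' Total masculinizer product of each individual
#'
#' Sums the expression levels of all masculinizer (M) alleles an individual
#' carries: up to two Y-linked and up to two autosomal alleles.
#'
#' @param pop Population matrix.
#' @return Numeric vector of cumulative M product per individual.
#' @export
total_m_product <- function(pop) {
  pop <- as_pop_matrix(pop)
  unname(pop[, "y_mat"] * pop[, "zmy_mat"] + pop[, "y_pat"] * pop[, "zmy_pat"] +
    pop[, "a_mat"] * pop[, "zma_mat"] + pop[, "a_pat"] * pop[, "zma_pat"])
}

#' Net expression of a single F allele
#'
#' Computes `(zf0 * (1 + beta * T) + eps) * (1 - sfm * zm_hat)`. The first
#' factor is the temperature-dependent amount of F product before
#' degradation; the second is the proportion not degraded by M product.
#' Each factor is floored at zero: noise cannot produce a negative amount
#' of product, and degradation cannot exceed the product present.
#'
#' @param z_f0 Baseline expression level(s) of the allele.
#' @param s_fm Sensitivity to M product, in \[0, 1\].
#' @param temp Normalized temperature in \[0, 1\].
#' @param z_m_hat Cumulative M product of the carrier.
#' @param eps Expression noise draw(s); default 0.
#' @param beta Temperature slope.
#' @return Numeric vector of net per-allele expression, >= 0.
#' @export
net_f_expression <- function(z_f0, s_fm, temp, z_m_hat, eps = 0, beta = 0) {
  if (any(temp < 0 | temp > 1)) stop("normalized temperature must be in [0, 1]")
  amount <- pmax(0, z_f0 * (1 + beta * temp) + eps)
  kept <- pmax(0, 1 - s_fm * z_m_hat)
  amount * kept
}

#' Determine phenotypic sex from genotype and temperature
#'
#' Draws one expression-noise value per F allele, sums the net expression
#' of both alleles ([net_f_expression()]), and compares the total with the
#' two thresholds: female above `theta_f`, male below `theta_m`, intersex
#' in between.
#'
#' @param pop Population matrix of undeveloped individuals.
#' @param temp Normalized temperature per individual (recycled).
#' @param params A [development_params()] object.
#' @return The population matrix with the `sex` column set.
#' @export
determine_sex <- function(pop, temp, params = development_params()) {
  pop <- as_pop_matrix(pop)
  if (any(pop[, "sex"] != SEX_UNDEVELOPED)) {
    stop("determine_sex() expects undeveloped individuals")
  }
  temp <- rep_len(as.numeric(temp), nrow(pop))
  if (any(temp < 0 | temp > 1)) stop("normalized temperature must be in [0, 1]")
  pop[, "sex"] <- cpp_determine_sex(pop, temp, params$theta_f,
                                    params$theta_m, params$beta,
                                    params$sigma_eps)
  pop
}

#' Y-chromosomal fitness factor
#'
#' Multiplicative fitness modifier from the Y chromosome: `s_yy` for YY
#' homozygotes, times `1 + s_a` for Y-bearing males or `1 - s_a` for
#' Y-bearing females (applied once per carrier, not per Y copy). Intersexes
#' experience only the YY viability component. The factor is floored at 0.
#'
#' @param pop Population matrix with developed individuals.
#' @param params A [fitness_params()] object.
#' @return Numeric vector of fitness multipliers.
#' @export
fitness_factor <- function(pop, params = fitness_params()) {
  pop <- as_pop_matrix(pop)
  if (any(pop[, "sex"] == SEX_UNDEVELOPED)) {
    stop("fitness_factor() expects developed individuals")
  }
  cpp_fitness_factor(pop, params$s_yy, params$s_a)
}
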