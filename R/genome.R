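# Population representation -------------------------------------------------
#
# A population is a plain numeric matrix with one row per individual and a
# fixed set of named columns. Every individual carries two F alleles (one
# maternal, one paternal), two sex-chromosome slots (X, or Y carrying the
# Y-linked masculinizer locus M_Y), and two autosomal masculinizer (M_A)
# slots that start empty and can be filled by de novo activation. Keeping
# everything numeric lets the simulation kernels run on the whole
# population at once.

#' Column names of the population matrix
#'
#' The population is stored as a numeric matrix with one row per individual.
#' Columns hold, per individual: deme index (0-based), phenotypic sex code
#' (0 = undeveloped, 1 = female, 2 = male, 3 = intersex), the maternal and
#' paternal F allele (baseline expression `zf0`, sensitivity `sfm`, and
#' their irreversible null-mutation flags), the two sex-chromosome slots
#' (`y_* = 1` for a Y, with the Y-linked masculinizer expression `zmy`),
#' and the two autosomal masculinizer slots (`a_* = 1` when occupied, with
#' expression `zma`).
#'
#' @return Character vector of column names, in matrix order.
#' @export
pop_columns <- function() {
  c("deme", "sex",
    "zf0_mat", "sfm_mat", "zf0_frozen_mat", "sfm_frozen_mat",
    "zf0_pat", "sfm_pat", "zf0_frozen_pat", "sfm_frozen_pat",
    "y_mat", "zmy_mat", "zmy_frozen_mat",
    "y_pat", "zmy_pat", "zmy_frozen_pat",
    "a_mat", "zma_mat", "zma_frozen_mat",
    "a_pat", "zma_pat", "zma_frozen_pat")
}

#' Column names of a gamete matrix
#'
#' A gamete carries exactly one allele per locus: one F allele, one
#' sex-chromosome (X or Y with its masculinizer), and one autosomal
#' masculinizer slot (possibly empty).
#'
#' @return Character vector of column names.
#' @export
gamete_columns <- function() {
  c("zf0", "sfm", "zf0_frozen", "sfm_frozen",
    "y", "zmy", "zmy_frozen",
    "a", "zma", "zma_frozen")
}

# Sex phenotype codes used throughout the package.
SEX_UNDEVELOPED <- 0L
SEX_FEMALE <- 1L
SEX_MALE <- 2L
SEX_INTERSEX <- 3L

#' Decode numeric sex codes to labels
#'
#' @param code Integer vector of sex codes (0-3).
#' @return Character vector with values `"undeveloped"`, `"female"`,
#'   `"male"`, `"intersex"`.
#' @export
sex_label <- function(code) {
  c("undeveloped", "female", "male", "intersex")[as.integer(code) + 1L]
}

#' Create an empty (all-zero) population matrix
#'
#' @param n Number of individuals (rows).
#' @return A numeric matrix with [pop_columns()] columns, all zero: every
#'   individual is undeveloped, in deme 0, XX, with null-free zero-valued
#'   alleles. Used as a scaffold by constructors; not a biologically
#'   meaningful population by itself.
#' @export
new_population <- function(n) {
  stopifnot(n >= 0)
  m <- matrix(0, nrow = n, ncol = length(pop_columns()),
              dimnames = list(NULL, pop_columns()))
  m
}

as_pop_matrix <- function(pop) {
  if (!is.matrix(pop) || !identical(colnames(pop), pop_columns())) {
    stop("expected a population matrix with pop_columns() columns")
  }
  pop
}

# Mutation parameters --------------------------------------------------------

#' Mutation parameters
#'
#' Per-gamete mutation model for the evolvable allelic traits. Each
#' transmitted trait mutates with probability `p_mut`; a fraction `p_null`
#' of mutations are null mutations that set the trait to zero irreversibly
#' (the trait is "frozen" and can never evolve again), the remainder add a
#' Gaussian step with standard deviation `sigma_mut`, clipped to the
#' trait's legal range. Independently, a gamete whose transmitted autosomal
#' masculinizer slot carries no expressed allele (the slot is empty, or
#' holds a decayed null allele) gains a fresh de novo M_A allele with
#' probability `mu_d`, with initial expression `z_m_init`; an expressed
#' M_A lineage is never overwritten.
#'
#' @param p_mut Per-trait, per-gamete mutation probability, in \[0, 1\].
#' @param p_null Fraction of mutations that are null, in \[0, 1\].
#' @param sigma_mut Standard deviation of regular mutational steps
#'   (expression units), >= 0.
#' @param mu_d De novo M_A activation probability per gamete, in \[0, 1\].
#' @param z_m_init Expression level of a newly activated M_A allele, >= 0.
#' @return A list of class `"gsd_mutation_params"`.
#' @export
mutation_params <- function(p_mut = 0.01, p_null = 0.05, sigma_mut = 0.05,
                            mu_d = 0, z_m_init = 1.0) {
  for (p in c(p_mut = p_mut, p_null = p_null, mu_d = mu_d)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("mutation probabilities must lie in [0, 1]")
    }
  }
  if (!is.finite(sigma_mut) || sigma_mut < 0) stop("sigma_mut must be >= 0")
  if (!is.finite(z_m_init) || z_m_init < 0) stop("z_m_init must be >= 0")
  structure(list(p_mut = p_mut, p_null = p_null, sigma_mut = sigma_mut,
                 mu_d = mu_d, z_m_init = z_m_init),
            class = "gsd_mutation_params")
}

trait_range <- function(trait = c("expression", "sensitivity")) {
  trait <- match.arg(trait)
  if (trait == "sensitivity") c(0, 1) else c(0, Inf)
}

#' Mutate allelic trait values
#'
#' Applies the per-gamete mutation model to a vector of trait values.
#' Frozen (null-mutated) traits are absorbing: they remain zero whatever
#' the parameters. Otherwise each value mutates with probability
#' `params$p_mut`; the mutation is a null mutation (value set to 0, trait
#' frozen forever) with probability `params$p_null`, and otherwise a
#' Gaussian step with sd `params$sigma_mut`, clipped to the trait's legal
#' range (\[0, 1\] for sensitivity, \[0, Inf) for expression levels).
#'
#' @param value Numeric vector of trait values.
#' @param frozen Logical (or 0/1 numeric) vector of null-mutation flags.
#' @param params A [mutation_params()] object.
#' @param trait `"expression"` or `"sensitivity"` (sets the legal range).
#' @return A list with components `value` (numeric) and `frozen` (logical).
#' @export
mutate_trait <- function(value, frozen = FALSE, params = mutation_params(),
                         trait = c("expression", "sensitivity")) {
  rng <- trait_range(match.arg(trait))
  frozen <- rep_len(as.numeric(frozen), length(value))
  bad <- !frozen & (value < rng[1] | value > rng[2])
  if (any(bad)) stop("trait value outside its legal range")
  out <- cpp_mutate_traits(as.numeric(value), frozen, rng[1], rng[2],
                           params$p_mut, params$p_null, params$sigma_mut)
  list(value = out$value, frozen = as.logical(out$frozen))
}

# Gamete formation and fertilization -----------------------------------------

#' Produce gametes from parents
#'
#' For each requested parent row, forms one haploid gamete: one of the two
#' alleles at each of the three loci is transmitted with probability 1/2
#' (the loci assort independently), the transmitted evolvable traits pass
#' through [mutate_trait()]'s model, and a transmitted autosomal slot
#' without an expressed allele is filled with a fresh M_A allele with
#' probability `params$mu_d` (see [mutation_params()]). Intersex and
#' undeveloped individuals never reproduce and are rejected.
#'
#' @param pop Population matrix.
#' @param rows Integer vector of parent row indices (may repeat).
#' @param params A [mutation_params()] object.
#' @return A numeric gamete matrix with [gamete_columns()] columns and
#'   `length(rows)` rows.
#' @export
make_gametes <- function(pop, rows, params = mutation_params()) {
  pop <- as_pop_matrix(pop)
  rows <- as.integer(rows)
  if (any(rows < 1 | rows > nrow(pop))) stop("parent row out of range")
  sx <- pop[rows, "sex"]
  if (any(sx == SEX_INTERSEX)) stop("intersex individuals cannot reproduce")
  if (any(sx == SEX_UNDEVELOPED)) stop("undeveloped individuals cannot reproduce")
  g <- cpp_make_gametes(pop, rows, params$p_mut, params$p_null,
                        params$sigma_mut, params$mu_d, params$z_m_init)
  colnames(g) <- gamete_columns()
  g
}

#' @rdname make_gametes
#' @param row A single parent row index.
#' @export
make_gamete <- function(pop, row, params = mutation_params()) {
  make_gametes(pop, row[1], params)
}

#' Fuse egg and sperm gametes into undeveloped offspring
#'
#' Egg alleles are tagged as maternal, sperm alleles as paternal. The
#' resulting individuals are undeveloped (sex code 0) and placed in their
#' natal deme.
#'
#' @param eggs Gamete matrix from mothers.
#' @param sperm Gamete matrix from fathers, same number of rows.
#' @param deme Integer vector (recycled) of natal deme indices, 0-based.
#' @return A population matrix of undeveloped offspring.
#' @export
fertilize <- function(eggs, sperm, deme = 0L) {
  if (nrow(eggs) != nrow(sperm)) stop("eggs and sperm must pair up 1:1")
  n <- nrow(eggs)
  off <- cbind(rep_len(as.numeric(deme), n), 0,
               eggs[, 1:4, drop = FALSE], sperm[, 1:4, drop = FALSE],
               eggs[, 5:7, drop = FALSE], sperm[, 5:7, drop = FALSE],
               eggs[, 8:10, drop = FALSE], sperm[, 8:10, drop = FALSE])
  colnames(off) <- pop_columns()
  off
}

#' Count Y chromosomes per individual
#'
#' @param pop Population matrix.
#' @return Integer vector (0, 1 or 2 per individual).
#' @export
n_y_chromosomes <- function(pop) {
  pop <- as_pop_matrix(pop)
  as.integer(pop[, "y_mat"] != 0) + as.integer(pop[, "y_pat"] != 0)
}
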