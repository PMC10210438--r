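# Result extraction: allele classes, SD-system taxonomy, clines --------------

traj_columns <- function() {
  c("generation", "deme", "temp",
    "n_female", "n_male", "n_intersex", "n_total",
    "freq_fi_mat_f", "freq_my_pat_m", "freq_ma_pat_m",
    "freq_f0_alleles", "freq_m_null", "mean_zf0", "mean_sfm")
}

# Fast per-deme summary as a plain numeric matrix; the exported
# summarize_generation() wraps this as a data frame. Frequencies over an
# empty denominator are NA.
summary_matrix <- function(pop, config, generation) {
  N <- config$n_demes
  eps <- config$eps_class
  cols <- traj_columns()
  out <- matrix(NA_real_, N, length(cols), dimnames = list(NULL, cols))
  out[, "generation"] <- generation
  out[, "deme"] <- seq_len(N) - 1
  out[, "temp"] <- deme_temperatures(N)
  out[, c("n_female", "n_male", "n_intersex", "n_total")] <- 0
  if (nrow(pop) == 0) return(out)
  idx <- as.integer(pop[, "deme"]) + 1L
  sex <- pop[, "sex"]
  wsum <- function(keep) tabulate(idx[keep], nbins = N)
  n_f <- wsum(sex == SEX_FEMALE)
  n_m <- wsum(sex == SEX_MALE)
  n_i <- wsum(sex == SEX_INTERSEX)
  n_t <- tabulate(idx, nbins = N)
  out[, "n_female"] <- n_f
  out[, "n_male"] <- n_m
  out[, "n_intersex"] <- n_i
  out[, "n_total"] <- n_t
  frac <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  fi_mat <- pop[, "zf0_mat"] > eps & pop[, "sfm_mat"] <= eps
  out[, "freq_fi_mat_f"] <- frac(wsum(sex == SEX_FEMALE & fi_mat), n_f)
  my_pat <- pop[, "y_pat"] != 0 & pop[, "zmy_pat"] > eps
  out[, "freq_my_pat_m"] <- frac(wsum(sex == SEX_MALE & my_pat), n_m)
  ma_pat <- pop[, "a_pat"] != 0 & pop[, "zma_pat"] > eps
  out[, "freq_ma_pat_m"] <- frac(wsum(sex == SEX_MALE & ma_pat), n_m)
  f0 <- wsum(pop[, "zf0_mat"] <= eps) + wsum(pop[, "zf0_pat"] <= eps)
  out[, "freq_f0_alleles"] <- frac(f0, 2 * n_t)
  m_pres <- (pop[, "y_mat"] != 0) + (pop[, "y_pat"] != 0) +
    (pop[, "a_mat"] != 0) + (pop[, "a_pat"] != 0)
  m_null <- (pop[, "y_mat"] != 0 & pop[, "zmy_mat"] <= eps) +
    (pop[, "y_pat"] != 0 & pop[, "zmy_pat"] <= eps) +
    (pop[, "a_mat"] != 0 & pop[, "zma_mat"] <= eps) +
    (pop[, "a_pat"] != 0 & pop[, "zma_pat"] <= eps)
  gsum <- function(w) {
    r <- rowsum(w, idx)
    v <- numeric(N)
    v[as.integer(rownames(r))] <- r
    v
  }
  out[, "freq_m_null"] <- frac(gsum(m_null), gsum(m_pres))
  out[, "mean_zf0"] <- frac(gsum(pop[, "zf0_mat"] + pop[, "zf0_pat"]), 2 * n_t)
  out[, "mean_sfm"] <- frac(gsum(pop[, "sfm_mat"] + pop[, "sfm_pat"]), 2 * n_t)
  out
}

#' Per-deme summary of a population
#'
#' Computes, per deme: phenotype counts; the frequency of insensitive
#' expressed F alleles (F_I) among maternally inherited F alleles of
#' females; the frequencies of expressed Y-linked and autosomal
#' masculinizers among paternally inherited alleles of males; the
#' population frequency of unexpressed F alleles (F_0) and of unexpressed
#' (null) masculinizer alleles; and mean F trait values. Frequencies with
#' an empty denominator (e.g. M frequencies in a deme without males) are
#' `NA`. The origin-filtered frequencies follow the sex-specific
#' transmission of the alleles: a dominant feminizer behaves like a
#' W chromosome (mother to daughter), masculinizers like a Y (father to
#' son).
#'
#' @param pop Population matrix.
#' @param config A [sim_config()] object (supplies deme count and the
#'   classification tolerance `eps_class`).
#' @param generation Generation number stored in the output.
#' @return A data frame with one row per deme.
#' @export
summarize_generation <- function(pop, config, generation = NA_integer_) {
  as.data.frame(summary_matrix(as_pop_matrix(pop), config, generation))
}

# F allele classes -----------------------------------------------------------

#' Classify F alleles
#'
#' Trinary classification of an F allele by its trait values: `"F_0"` if
#' effectively unexpressed (`z_f0 <= eps_class`), else `"F_I"` if
#' effectively insensitive to M product (`s_fm <= eps_class`), else
#' `"F"` (regular: expressed and sensitive). An unexpressed allele cannot
#' feminize, so `"F_0"` takes precedence over `"F_I"`.
#'
#' @param z_f0 Baseline expression value(s).
#' @param s_fm Sensitivity value(s).
#' @param eps_class Positive classification tolerance; evolved continuous
#'   traits never hit exact zero without null mutations, so values at or
#'   below the tolerance count as zero.
#' @return Character vector in `c("F", "F_I", "F_0")`.
#' @export
classify_f_allele <- function(z_f0, s_fm, eps_class = 0.01) {
  stopifnot(eps_class > 0)
  ifelse(z_f0 <= eps_class, "F_0", ifelse(s_fm <= eps_class, "F_I", "F"))
}

# Genotype classes ------------------------------------------------------------

# Per-individual classification into the discrete genotype vocabulary:
# an unordered pair of F classes, of sex-chromosome states (X, YM =
# Y with expressed masculinizer, Y0 = Y with unexpressed masculinizer),
# and of autosomal states (M = expressed masculinizer, 0 = empty slot or
# unexpressed allele).

#' Discrete genotype class of each individual
#'
#' Encodes each individual as `"f1/f2; s1/s2; a1/a2"` where the F classes
#' come from [classify_f_allele()], sex-chromosome slots are `X`, `YM`
#' (Y carrying an expressed masculinizer) or `Y0` (Y with an unexpressed
#' one), and autosomal slots are `M` (expressed masculinizer) or `0`.
#' Slots within a locus are sorted, so the class is unordered with respect
#' to parental origin.
#'
#' @param pop Population matrix.
#' @param eps_class Classification tolerance.
#' @return Character vector of genotype class strings.
#' @export
genotype_class <- function(pop, eps_class = 0.01) {
  pop <- as_pop_matrix(pop)
  f1 <- classify_f_allele(pop[, "zf0_mat"], pop[, "sfm_mat"], eps_class)
  f2 <- classify_f_allele(pop[, "zf0_pat"], pop[, "sfm_pat"], eps_class)
  sc <- function(y, zmy) {
    ifelse(y == 0, "X", ifelse(zmy > eps_class, "YM", "Y0"))
  }
  s1 <- sc(pop[, "y_mat"], pop[, "zmy_mat"])
  s2 <- sc(pop[, "y_pat"], pop[, "zmy_pat"])
  au <- function(a, zma) ifelse(a != 0 & zma > eps_class, "M", "0")
  a1 <- au(pop[, "a_mat"], pop[, "zma_mat"])
  a2 <- au(pop[, "a_pat"], pop[, "zma_pat"])
  pair <- function(x, y) {
    ifelse(x <= y, paste0(x, "/", y), paste0(y, "/", x))
  }
  paste0(pair(f1, f2), "; ", pair(s1, s2), "; ", pair(a1, a2))
}

parse_genotype_class <- function(cls) {
  parts <- strsplit(cls, "; ", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("malformed genotype class: ", cls)
  split2 <- function(x) strsplit(x, "/", fixed = TRUE)[[1]]
  list(f = split2(parts[1]), s = split2(parts[2]), a = split2(parts[3]))
}

#' Most prevalent genotype class per sex
#'
#' Returns the most frequent genotype class among females and among males.
#' Ties are broken lexicographically (smallest class string wins).
#'
#' @param pop Population matrix with developed individuals.
#' @param eps_class Classification tolerance.
#' @return A list with components `female` and `male` (class strings).
#' @export
modal_genotype_pair <- function(pop, eps_class = 0.01) {
  pop <- as_pop_matrix(pop)
  modal <- function(rows, label) {
    if (length(rows) == 0) {
      stop("degenerate population: no ", label, " present")
    }
    tab <- table(genotype_class(pop[rows, , drop = FALSE], eps_class))
    winners <- sort(names(tab)[tab == max(tab)])
    winners[1]
  }
  list(female = modal(which(pop[, "sex"] == SEX_FEMALE), "females"),
       male = modal(which(pop[, "sex"] == SEX_MALE), "males"))
}

# SD-system classification ----------------------------------------------------

# Phenotypic sex implied by a genotype class under the class-level
# abstraction: insensitive expressed alleles (F_I) always contribute one
# allele's activity z_f; regular F alleles contribute z_f only when no
# expressed masculinizer is present (M degrades them fully at the class
# level); unexpressed alleles contribute nothing.
class_sex <- function(f, m_expressed, z_f, theta_m, theta_f) {
  contrib <- sum(f == "F_I") + if (m_expressed) 0L else sum(f == "F")
  zhat <- contrib * z_f
  if (zhat > theta_f) "female" else if (zhat < theta_m) "male" else "intersex"
}

class_gametes <- function(g) {
  out <- vector("list", 8)
  k <- 0
  for (fi in 1:2) for (si in 1:2) for (ai in 1:2) {
    k <- k + 1
    out[[k]] <- c(f = g$f[fi], s = g$s[si], a = g$a[ai])
  }
  out
}

canonical_class <- function(f, s, a, mask_m = FALSE) {
  pair <- function(x) paste(sort(x), collapse = "/")
  if (mask_m) {
    paste0(pair(f), "; */*; */*")
  } else {
    paste0(pair(f), "; ", pair(s), "; ", pair(a))
  }
}

#' Label for the ordering of single-allele F activity and the thresholds
#'
#' @param z_f Maximum potential activity of a single F allele
#'   (`z_f0 * (1 + beta * T)` for the temperature of interest).
#' @param theta_m,theta_f Sex-determination thresholds.
#' @return One of `"zF<thetaM<thetaF"`, `"thetaM<zF<thetaF"`,
#'   `"thetaM<thetaF<zF"`.
#' @export
regime_label <- function(z_f, theta_m, theta_f) {
  stopifnot(theta_m < theta_f)
  if (z_f < theta_m) "zF<thetaM<thetaF"
  else if (z_f > theta_f) "thetaM<thetaF<zF"
  else "thetaM<zF<thetaF"
}

#' Classify a sex-determination system from its genotype pair
#'
#' A named SD system is a recurrent pair of female and male genotype
#' classes: matings within the pair regenerate only those two classes,
#' with the correct sexes and without intersexes. Recurrence is verified
#' by brute-force enumeration of all offspring genotype classes (each
#' parent transmits one of its two alleles per locus, independently).
#' Offspring sex is evaluated at the class level: F_I alleles contribute
#' activity `z_f` regardless of M, regular F alleles contribute `z_f`
#' only in the absence of expressed M, and the summed activity is
#' compared with the thresholds. In systems where no regular (sensitive,
#' expressed) F allele occurs in either genotype, M has no phenotypic
#' function; its slots are then masked as `*` and ignored by the
#' recurrence check.
#'
#' Known recurrent pairs map to named systems: ancestral-style male
#' heterogamety through a single expressed masculinizer (Y-linked or
#' autosomal), dominant-F_I female heterogamety with M fixed, dominant-F_I
#' female heterogamety with degenerate M, and recessive-F_I male
#' heterogamety in which the unexpressed allele F_0 acts as a dominant
#' male-determiner. Other recurrent pairs are labelled
#' `"other_recurrent"`; non-recurrent pairs are `"unclassified"`.
#'
#' @param pair List with `female` and `male` genotype class strings, as
#'   returned by [modal_genotype_pair()].
#' @param z_f Activity of a single expressed F allele under the local
#'   conditions.
#' @param theta_m,theta_f Sex-determination thresholds.
#' @return A list of class `"gsd_sd_system"` with elements `female`,
#'   `male` (possibly M-masked class strings), `label`, `recurrent`,
#'   and `regime` (from [regime_label()]).
#' @export
classify_sd_system <- function(pair, z_f, theta_m, theta_f) {
  fem <- parse_genotype_class(pair$female)
  mal <- parse_genotype_class(pair$male)
  mask_m <- !("F" %in% c(fem$f, mal$f))
  fem_cls <- canonical_class(fem$f, fem$s, fem$a, mask_m)
  mal_cls <- canonical_class(mal$f, mal$s, mal$a, mask_m)
  recurrent <- FALSE
  if (fem_cls != mal_cls) {
    recurrent <- TRUE
    seen_female <- FALSE
    seen_male <- FALSE
    for (egg in class_gametes(fem)) {
      for (sperm in class_gametes(mal)) {
        f <- c(egg[["f"]], sperm[["f"]])
        s <- c(egg[["s"]], sperm[["s"]])
        a <- c(egg[["a"]], sperm[["a"]])
        m_exp <- any(s == "YM") || any(a == "M")
        sx <- class_sex(f, m_exp, z_f, theta_m, theta_f)
        cls <- canonical_class(f, s, a, mask_m)
        ok <- (sx == "female" && cls == fem_cls) ||
              (sx == "male" && cls == mal_cls)
        if (!ok) {
          recurrent <- FALSE
          break
        }
        if (sx == "female") seen_female <- TRUE else seen_male <- TRUE
      }
      if (!recurrent) break
    }
    if (recurrent && !(seen_female && seen_male)) recurrent <- FALSE
  }
  label <- "unclassified"
  if (recurrent) {
    label <- "other_recurrent"
    fs <- sort(fem$f); ms <- sort(mal$f)
    n_exp_m <- function(g) sum(g$s == "YM") + sum(g$a == "M")
    if (mask_m) {
      if (identical(fs, c("F_I", "F_I")) && identical(ms, c("F_0", "F_I"))) {
        label <- "male_heterogamety_F0"
      } else if (identical(fs, c("F_0", "F_I")) &&
                 identical(ms, c("F_0", "F_0"))) {
        label <- "female_heterogamety_FI_degenerate_M"
      }
    } else {
      all_F <- function(g) all(g == c("F", "F"))
      if (all_F(fs) && all_F(ms) && n_exp_m(fem) == 0 && n_exp_m(mal) == 1) {
        label <- if (any(mal$s == "YM")) "male_heterogamety_MY"
                 else "male_heterogamety_MA"
      } else if (identical(fs, c("F", "F_I")) && all_F(ms) &&
                 n_exp_m(fem) >= 1 && n_exp_m(mal) >= 1) {
        label <- "female_heterogamety_FI"
      }
    }
  }
  structure(list(female = fem_cls, male = mal_cls, label = label,
                 recurrent = recurrent,
                 regime = regime_label(z_f, theta_m, theta_f)),
            class = "gsd_sd_system")
}

#' @export
print.gsd_sd_system <- function(x, ...) {
  cat(sprintf("<gsd_sd_system> %s (%srecurrent; regime %s)\n  F: %s\n  M: %s\n",
              x$label, if (x$recurrent) "" else "not ", x$regime,
              x$female, x$male))
  invisible(x)
}

# Equilibrium summaries and housefly-like detection ---------------------------

#' Window-averaged equilibrium summary of a trajectory
#'
#' Averages the recorded per-deme frequencies over the final fraction
#' `window` of recorded generations (`NA` records are dropped from the
#' averages; a deme-quantity with no data in the window stays `NA`).
#'
#' @param trajectory Trajectory data frame from [run_simulation()].
#' @param window Fraction of recorded generations to average over,
#'   in (0, 1\].
#' @return Data frame with one row per deme: `deme`, `temp`, window-mean
#'   phenotype counts and allele frequencies.
#' @export
equilibrium_summary <- function(trajectory, window = 0.1) {
  stopifnot(window > 0, window <= 1)
  gens <- sort(unique(trajectory$generation))
  n_keep <- max(1L, ceiling(window * length(gens)))
  keep_gens <- gens[(length(gens) - n_keep + 1L):length(gens)]
  tr <- trajectory[trajectory$generation %in% keep_gens, , drop = FALSE]
  num_cols <- setdiff(traj_columns(), c("generation", "deme", "temp"))
  ag <- aggregate(tr[num_cols], by = list(deme = tr$deme, temp = tr$temp),
                  FUN = function(x) {
                    x <- x[!is.na(x)]
                    if (length(x) == 0) NA_real_ else mean(x)
                  })
  ag[order(ag$deme), , drop = FALSE]
}

#' Detect a housefly-like polymorphic SD system
#'
#' A housefly-like system shows three joint clines at equilibrium: the
#' Y-linked masculinizer is the major paternally inherited allele in males
#' at the cold end (T = 0) but the minor one at the warm end (T = 1),
#' while both the autosomal masculinizer (paternal alleles in males) and
#' the dominant feminizer F_I (maternal alleles in females) are minor at
#' the cold end and major at the warm end. "Major" means a window-averaged
#' frequency above 0.5.
#'
#' @param trajectory Trajectory data frame covering the first and last
#'   deme.
#' @param window Fraction of recorded generations to average over.
#' @return `TRUE` or `FALSE`.
#' @export
detect_housefly_like <- function(trajectory, window = 0.1) {
  eq <- equilibrium_summary(trajectory, window)
  cold <- eq[eq$deme == min(eq$deme), , drop = FALSE]
  warm <- eq[eq$deme == max(eq$deme), , drop = FALSE]
  need <- c(cold$freq_my_pat_m, warm$freq_my_pat_m,
            cold$freq_ma_pat_m, warm$freq_ma_pat_m,
            cold$freq_fi_mat_f, warm$freq_fi_mat_f)
  if (length(need) != 6 || anyNA(need)) {
    stop("insufficient data: edge-deme frequencies missing in the window")
  }
  cold$freq_my_pat_m > 0.5 && warm$freq_my_pat_m < 0.5 &&
    cold$freq_ma_pat_m < 0.5 && warm$freq_ma_pat_m > 0.5 &&
    cold$freq_fi_mat_f < 0.5 && warm$freq_fi_mat_f > 0.5
}

#' Analyze a finished simulation
#'
#' Convenience wrapper combining the window-averaged equilibrium summary,
#' the modal-genotype SD-system call (evaluated at both gradient ends),
#' and the housefly-like verdict.
#'
#' @param sim A `"gsd_simulation"` object.
#' @param window Averaging window (fraction of recorded generations).
#' @return A list with `equilibrium` (data frame), `sd_system_cold`,
#'   `sd_system_warm` (`"gsd_sd_system"` or `NULL` for degenerate
#'   populations), and `housefly_like` (logical or `NA` when edge data
#'   are missing).
#' @export
analyze_simulation <- function(sim, window = sim$config$eq_window) {
  cfg <- sim$config
  eq <- equilibrium_summary(sim$trajectory, window)
  call_at <- function(temp, deme) {
    sub <- sim$final_pop[sim$final_pop[, "deme"] == deme, , drop = FALSE]
    pair <- tryCatch(modal_genotype_pair(sub, cfg$eps_class),
                     error = function(e) NULL)
    if (is.null(pair)) return(NULL)
    # single-allele activity from the deme's evolved expression levels
    zf0s <- c(sub[, "zf0_mat"], sub[, "zf0_pat"])
    zf0s <- zf0s[zf0s > cfg$eps_class]
    z_f0 <- if (length(zf0s) == 0) cfg$z_f0_init else mean(zf0s)
    classify_sd_system(pair, z_f = z_f0 * (1 + cfg$beta * temp),
                       theta_m = cfg$theta_m, theta_f = cfg$theta_f)
  }
  hf <- tryCatch(detect_housefly_like(sim$trajectory, window),
                 error = function(e) NA)
  list(equilibrium = eq,
       sd_system_cold = call_at(0, 0),
       sd_system_warm = call_at(1, cfg$n_demes - 1),
       housefly_like = hf)
}
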