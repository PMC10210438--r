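# Deterministic population builders for tests and examples -------------------
#
# Genotype shorthand: "<F>/<F>; <M>/<M>", e.g. "F/F; +/M_Y" or
# "F_I/F; M_A/M_A". The first token of each pair is the maternally
# inherited allele, the second the paternally inherited one. F tokens are
# F (expressed, sensitive), F_I (expressed, insensitive) and F_0
# (unexpressed). M tokens describe everything a gamete of that origin
# contributed besides the F allele: "+" (X chromosome, no autosomal M),
# "M_Y" (Y with expressed masculinizer), "Y0" (Y with a null masculinizer),
# "M_A" (X plus an expressed autosomal masculinizer), and composites like
# "M_Y+M_A" for a Y plus an autosomal M from the same parent.

F_TOKENS <- c("F", "F_I", "F_0")

parse_m_token <- function(token, spec, pos) {
  out <- list(y = 0, zmy_expressed = FALSE, a = 0, zma_expressed = FALSE)
  if (token == "+") return(out)
  for (part in strsplit(token, "+", fixed = TRUE)[[1]]) {
    if (part == "M_Y") {
      if (out$y != 0) stop_parse(spec, pos, "duplicate Y chromosome token")
      out$y <- 1; out$zmy_expressed <- TRUE
    } else if (part == "Y0") {
      if (out$y != 0) stop_parse(spec, pos, "duplicate Y chromosome token")
      out$y <- 1; out$zmy_expressed <- FALSE
    } else if (part == "M_A") {
      if (out$a != 0) stop_parse(spec, pos, "duplicate autosomal M token")
      out$a <- 1; out$zma_expressed <- TRUE
    } else if (part == "A0") {
      if (out$a != 0) stop_parse(spec, pos, "duplicate autosomal M token")
      out$a <- 1; out$zma_expressed <- FALSE
    } else {
      stop_parse(spec, pos, paste0("unknown M token '", part, "'"))
    }
  }
  out
}

stop_parse <- function(spec, pos, why) {
  stop(sprintf("cannot parse genotype '%s' at field %d: %s", spec, pos, why))
}

#' Build one individual from genotype shorthand
#'
#' @param spec Genotype shorthand string, e.g. `"F/F; +/M_Y"` (an
#'   ancestral XY male genotype) or `"F_I/F; M_A/M_A"` (a dominant-F_I
#'   carrier with the autosomal masculinizer fixed). See the package
#'   vignette for the grammar.
#' @param deme Natal deme index (0-based).
#' @param z_f0 Baseline expression assigned to expressed F alleles.
#' @param s_fm Sensitivity assigned to sensitive F alleles.
#' @param z_m Expression assigned to expressed masculinizer alleles.
#' @return A one-row population matrix; the individual is undeveloped.
#' @export
build_individual <- function(spec, deme = 0L, z_f0 = 1, s_fm = 1, z_m = 1) {
  fields <- strsplit(spec, ";")[[1]]
  if (length(fields) != 2) {
    stop_parse(spec, length(fields),
               "expected two ';'-separated fields (F pair; M pair)")
  }
  fields <- trimws(fields)
  f_tokens <- trimws(strsplit(fields[1], "/", fixed = TRUE)[[1]])
  if (length(f_tokens) != 2) {
    stop_parse(spec, 1, "the F field must hold exactly two '/'-separated alleles")
  }
  if (!all(f_tokens %in% F_TOKENS)) {
    stop_parse(spec, 1, paste0("unknown F token '",
                               setdiff(f_tokens, F_TOKENS)[1], "'"))
  }
  m_tokens <- trimws(strsplit(fields[2], "/", fixed = TRUE)[[1]])
  if (length(m_tokens) != 2) {
    stop_parse(spec, 2, "the M field must hold exactly two '/'-separated slots")
  }
  pop <- new_population(1)
  pop[, "deme"] <- deme
  origin <- c("mat", "pat")
  for (k in 1:2) {
    o <- origin[k]
    tok <- f_tokens[k]
    pop[, paste0("zf0_", o)] <- if (tok == "F_0") 0 else z_f0
    pop[, paste0("zf0_frozen_", o)] <- as.numeric(tok == "F_0")
    pop[, paste0("sfm_", o)] <- if (tok == "F_I") 0 else s_fm
    pop[, paste0("sfm_frozen_", o)] <- as.numeric(tok == "F_I")
    m <- parse_m_token(m_tokens[k], spec, 2)
    pop[, paste0("y_", o)] <- m$y
    pop[, paste0("zmy_", o)] <- if (m$y != 0 && m$zmy_expressed) z_m else 0
    pop[, paste0("zmy_frozen_", o)] <- as.numeric(m$y != 0 && !m$zmy_expressed)
    pop[, paste0("a_", o)] <- m$a
    pop[, paste0("zma_", o)] <- if (m$a != 0 && m$zma_expressed) z_m else 0
    pop[, paste0("zma_frozen_", o)] <- as.numeric(m$a != 0 && !m$zma_expressed)
  }
  pop
}

#' Build a developed deme from genotype shorthand
#'
#' Replicates each genotype `counts` times and develops all individuals at
#' temperature `temp` with expression noise switched off, so the resulting
#' phenotypes are deterministic.
#'
#' @param specs Character vector of genotype shorthand strings.
#' @param counts Integer vector of copies per genotype (recycled).
#' @param temp Normalized temperature of the deme.
#' @param deme Deme index (0-based).
#' @param dev A [development_params()] object; its `sigma_eps` is forced
#'   to 0.
#' @param ... Trait values passed on to [build_individual()].
#' @return A developed population matrix.
#' @export
build_deme <- function(specs, counts = 1L, temp = 0, deme = 0L,
                       dev = development_params(), ...) {
  counts <- rep_len(as.integer(counts), length(specs))
  stopifnot(all(counts >= 0))
  rows <- mapply(function(s, k) {
    ind <- build_individual(s, deme = deme, ...)
    ind[rep.int(1L, k), , drop = FALSE]
  }, specs, counts, SIMPLIFY = FALSE)
  pop <- do.call(rbind, c(list(new_population(0)), rows))
  if (nrow(pop) == 0) return(pop)
  dev0 <- development_params(theta_f = dev$theta_f, theta_m = dev$theta_m,
                             beta = dev$beta, sigma_eps = 0)
  determine_sex(pop, temp, dev0)
}

# Snapshot TSV ---------------------------------------------------------------
# One row per allele copy, so snapshots stay human-readable and diffable.

#' Write a population snapshot as TSV
#'
#' One row per allele copy: individual id, deme, sex, locus (`F`, `SC` for
#' the sex-chromosome slot, `A` for the autosomal masculinizer slot),
#' parental origin, a presence flag (a `SC` row with `present = 0` is an
#' X chromosome; an `A` row with `present = 0` is an empty slot), trait
#' values and null-mutation flags.
#'
#' @param pop Population matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(pop, path) {
  pop <- as_pop_matrix(pop)
  n <- nrow(pop)
  rows <- list()
  for (o in c("mat", "pat")) {
    rows[[paste0("F", o)]] <- data.frame(
      individual = seq_len(n), deme = pop[, "deme"], sex = pop[, "sex"],
      locus = "F", origin = o, present = 1,
      value1 = pop[, paste0("zf0_", o)], value2 = pop[, paste0("sfm_", o)],
      frozen1 = pop[, paste0("zf0_frozen_", o)],
      frozen2 = pop[, paste0("sfm_frozen_", o)])
    rows[[paste0("SC", o)]] <- data.frame(
      individual = seq_len(n), deme = pop[, "deme"], sex = pop[, "sex"],
      locus = "SC", origin = o, present = pop[, paste0("y_", o)],
      value1 = pop[, paste0("zmy_", o)], value2 = NA_real_,
      frozen1 = pop[, paste0("zmy_frozen_", o)], frozen2 = NA_real_)
    rows[[paste0("A", o)]] <- data.frame(
      individual = seq_len(n), deme = pop[, "deme"], sex = pop[, "sex"],
      locus = "A", origin = o, present = pop[, paste0("a_", o)],
      value1 = pop[, paste0("zma_", o)], value2 = NA_real_,
      frozen1 = pop[, paste0("zma_frozen_", o)], frozen2 = NA_real_)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$individual, out$locus, out$origin), , drop = FALSE]
  # full double precision so snapshots round-trip bit-exactly
  for (col in c("value1", "value2")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.17g", out[[col]]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population snapshot written by [write_snapshot()]
#'
#' @param path Snapshot TSV path.
#' @return A population matrix.
#' @export
read_snapshot <- function(path) {
  snap <- read.delim(path, stringsAsFactors = FALSE)
  ids <- sort(unique(snap$individual))
  pop <- new_population(length(ids))
  take <- function(locus, origin) {
    r <- snap[snap$locus == locus & snap$origin == origin, , drop = FALSE]
    r[match(ids, r$individual), , drop = FALSE]
  }
  first <- take("F", "mat")
  pop[, "deme"] <- first$deme
  pop[, "sex"] <- first$sex
  for (o in c("mat", "pat")) {
    f <- take("F", o)
    pop[, paste0("zf0_", o)] <- f$value1
    pop[, paste0("sfm_", o)] <- f$value2
    pop[, paste0("zf0_frozen_", o)] <- f$frozen1
    pop[, paste0("sfm_frozen_", o)] <- f$frozen2
    s <- take("SC", o)
    pop[, paste0("y_", o)] <- s$present
    pop[, paste0("zmy_", o)] <- s$value1
    pop[, paste0("zmy_frozen_", o)] <- s$frozen1
    a <- take("A", o)
    pop[, paste0("a_", o)] <- a$present
    pop[, paste0("zma_", o)] <- a$value1
    pop[, paste0("zma_frozen_", o)] <- a$frozen1
  }
  pop
}
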