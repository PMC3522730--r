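#' Configuration for the synthetic case-control cohort generator
#'
#' Defaults emulate the study design the analysis targets: 494 cases and 536
#' controls drawn from two ethnic groups (about 19% / 81%), controls
#' frequency matched to cases by 5-year age bin and ethnicity, ages centred
#' at 65.9 (SD 8.4) years truncated to 40-90, three recruiting institutions,
#' tag SNPs with MAF above 0.05 correlated within genes (latent AR(1)
#' correlation 0.5), two-population allele-frequency differentiation at
#' Fst 0.15 (Balding-Nichols), and 39 ancestry-informative markers with a
#' mean between-group frequency differential of 0.3.
#'
#' @param n_cases,n_controls Target subject counts.
#' @param p_group2 Fraction of the cohort from the minority population.
#' @param fst Balding-Nichols differentiation of the pathway SNPs.
#' @param ld_rho Latent AR(1) correlation of SNPs within a gene.
#' @param maf_range Ancestral-frequency range for pathway SNPs.
#' @param n_aims,aim_delta Number of ancestry-informative markers and their
#'   between-population frequency differential.
#' @param effect_or Named vector of per-allele odds ratios (names are SNP ids
#'   of the annotation); empty for a global-null cohort.
#' @param causal_maf Ancestral frequency forced on SNPs in `effect_or`.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param n_institutions Number of recruiting sites.
#' @param age_beta,ethnicity_beta Log-odds effects of (centred) age and of
#'   minority-group membership on disease.
#' @param age_bin Width in years of the matching age bins.
#' @param missing_rate Per-call missingness rate of the emitted genotypes.
#' @param pool_mult Simulated-pool size as a multiple of the cohort size.
#' @param annotation Annotation to realise; default the packaged 46-gene /
#'   320-SNP / 39-AIM fixture.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 494, n_controls = 536, p_group2 = 0.19,
                       fst = 0.15, ld_rho = 0.5, maf_range = c(0.05, 0.5),
                       n_aims = 39, aim_delta = 0.3,
                       effect_or = numeric(0), causal_maf = 0.3,
                       age_mean = 65.9, age_sd = 8.4,
                       age_range = c(40, 90), n_institutions = 3,
                       age_beta = 0, ethnicity_beta = 0, age_bin = 5,
                       missing_rate = 0, pool_mult = 6,
                       annotation = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cases >= 1, n_controls >= 1, p_group2 >= 0, p_group2 <= 1,
            fst >= 0, fst < 1, abs(ld_rho) < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            aim_delta >= 0, aim_delta <= 1,
            causal_maf > 0, causal_maf < 1,
            missing_rate >= 0, missing_rate < 1, pool_mult >= 1)
  if (length(effect_or) && is.null(names(effect_or)))
    stop("effect_or must be a named vector (names are SNP ids)")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 p_group2 = p_group2, fst = fst, ld_rho = ld_rho,
                 maf_range = maf_range, n_aims = n_aims,
                 aim_delta = aim_delta, effect_or = effect_or,
                 causal_maf = causal_maf, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 n_institutions = n_institutions, age_beta = age_beta,
                 ethnicity_beta = ethnicity_beta, age_bin = age_bin,
                 missing_rate = missing_rate, pool_mult = pool_mult,
                 annotation = annotation, seed = as.integer(seed)),
            class = "sim_config")
}

#' Balding-Nichols subpopulation allele frequencies
#'
#' Draws per-population frequencies from
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)`, whose mean is the ancestral
#' frequency `p` and whose variance is `F p (1 - p)`. `F = 0` returns the
#' ancestral frequency exactly.
#'
#' @param p Ancestral allele frequency in (0, 1).
#' @param fst Fixation index in `[0, 1)`.
#' @param n_pops Number of populations.
#' @return Numeric vector of length `n_pops`.
#' @export
balding_nichols_freqs <- function(p, fst, n_pops = 2) {
  if (p <= 0 || p >= 1) stop("ancestral frequency must be in (0, 1)")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (fst == 0) return(rep(p, n_pops))
  stats::rbeta(n_pops, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate a block of LD-correlated genotypes
#'
#' Two latent AR(1) Gaussian haplotypes per individual are thresholded at
#' each SNP's frequency quantile and summed, giving genotypes in
#' Hardy-Weinberg proportions whose pairwise r-squared decays with distance
#' along the block.
#'
#' @param n Number of individuals.
#' @param mafs Per-SNP allele frequencies (the thresholded, counted allele).
#' @param ld_rho Latent AR(1) correlation, `|ld_rho| < 1`.
#' @return Integer matrix `n x length(mafs)` of 0/1/2 counts.
#' @export
simulate_ld_genotypes <- function(n, mafs, ld_rho = 0) {
  if (abs(ld_rho) >= 1) stop("|ld_rho| must be below 1")
  if (any(mafs <= 0 | mafs >= 1)) stop("allele frequencies must be in (0, 1)")
  p <- length(mafs)
  thr <- stats::qnorm(mafs)
  hap <- function() {
    Z <- matrix(stats::rnorm(n * p), n, p)
    if (p > 1 && ld_rho != 0)
      for (j in 2:p) Z[, j] <- ld_rho * Z[, j - 1] +
          sqrt(1 - ld_rho^2) * Z[, j]
    sweep(Z, 2, thr, "<=") + 0
  }
  hap() + hap()
}

# truncated-normal ages via inverse-CDF sampling
.sim_ages <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# largest-remainder integer allocation of `total` proportional to `weights`
.allocate <- function(weights, total) {
  if (sum(weights) == 0) stop("cannot allocate: all weights zero")
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate a two-population case-control cohort
#'
#' Generates a subject pool from two populations, draws ages, institutions
#' and LD-structured genotypes (per-gene blocks with Balding-Nichols
#' population frequencies, plus ancestry-informative markers with a
#' configured frequency differential), assigns disease through a logistic
#' model whose intercept is calibrated by bisection to the target case
#' fraction, samples the requested number of cases, and frequency-matches
#' controls to the cases by age bin and ethnicity.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (a `genotype_matrix`), `samples` (sample
#'   table), `annotation` (the realised annotation), and `pop_freqs`
#'   (per-SNP per-population frequencies).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  annot <- config$annotation
  if (is.null(annot)) annot <- pathway_annotation()
  snp <- annot[!annot$is_aim, , drop = FALSE]
  aims <- annot[annot$is_aim, , drop = FALSE]
  if (nrow(aims) > config$n_aims) aims <- aims[seq_len(config$n_aims), ]
  unknown <- setdiff(names(config$effect_or), snp$snp_id)
  if (length(unknown))
    stop("effect_or names not in annotation: ",
         paste(unknown, collapse = ", "))

  n_target <- config$n_cases + config$n_controls
  N <- ceiling(config$pool_mult * n_target)
  eth <- ifelse(stats::runif(N) < config$p_group2, "group2", "group1")
  age <- .sim_ages(N, config$age_mean, config$age_sd, config$age_range)
  inst <- sample(sprintf("site%d", seq_len(config$n_institutions)), N,
                 replace = TRUE)

  # per-population allele frequencies for pathway SNPs
  anc <- stats::runif(nrow(snp), config$maf_range[1], config$maf_range[2])
  anc[snp$snp_id %in% names(config$effect_or)] <- config$causal_maf
  pf <- t(vapply(anc, balding_nichols_freqs, numeric(2), fst = config$fst))
  pf <- pmin(pmax(pf, 0.01), 0.99)
  colnames(pf) <- c("group1", "group2")

  G <- matrix(0, N, nrow(snp), dimnames = list(NULL, snp$snp_id))
  blocks <- split(seq_len(nrow(snp)), snp$gene)
  for (g in names(blocks)) {
    cols <- blocks[[g]]
    for (pop in c("group1", "group2")) {
      idx <- which(eth == pop)
      if (length(idx))
        G[idx, cols] <- simulate_ld_genotypes(length(idx), pf[cols, pop],
                                              config$ld_rho)
    }
  }

  # AIMs: independent, configured between-population differential
  A <- NULL
  if (nrow(aims)) {
    base <- stats::runif(nrow(aims), 0.25, 0.75)
    f1 <- pmin(pmax(base - config$aim_delta / 2, 0.02), 0.98)
    f2 <- pmin(pmax(base + config$aim_delta / 2, 0.02), 0.98)
    A <- matrix(0, N, nrow(aims), dimnames = list(NULL, aims$snp_id))
    for (pop in c("group1", "group2")) {
      idx <- which(eth == pop)
      f <- if (pop == "group1") f1 else f2
      if (length(idx))
        A[idx, ] <- matrix(stats::rbinom(length(idx) * nrow(aims), 2,
                                         rep(f, each = length(idx))),
                           length(idx))
    }
  }

  beta <- log(config$effect_or)
  eta_gen <- if (length(beta))
    drop(G[, names(beta), drop = FALSE] %*% beta) else numeric(N)
  eta_cov <- config$age_beta * (age - config$age_mean) +
    config$ethnicity_beta * (eth == "group2")
  target_frac <- config$n_cases / n_target
  b0 <- stats::uniroot(function(b)
    mean(stats::plogis(b + eta_gen + eta_cov)) - target_frac,
    c(-30, 30), tol = 1e-10)$root
  y <- stats::rbinom(N, 1, stats::plogis(b0 + eta_gen + eta_cov))

  case_pool <- which(y == 1)
  if (length(case_pool) < config$n_cases)
    stop("matching infeasible: pool has only ", length(case_pool),
         " cases; increase pool_mult")
  cases <- case_pool[sample.int(length(case_pool), config$n_cases)]

  agebin <- function(i) floor((age[i] - config$age_range[1]) /
                                config$age_bin)
  bin <- function(i) paste(eth[i], agebin(i), sep = ":")
  case_bins <- table(bin(cases))
  want <- .allocate(as.numeric(case_bins), config$n_controls)
  names(want) <- names(case_bins)
  ctrl_pool <- which(y == 0)
  ctrl_bin <- bin(ctrl_pool)
  ctrl_eth <- eth[ctrl_pool]
  ctrl_age <- agebin(ctrl_pool)
  used <- rep(FALSE, length(ctrl_pool))
  controls <- integer(0)
  for (b in names(want)) {
    free <- which(ctrl_bin == b & !used)
    take <- utils::head(free[sample.int(length(free))], want[[b]])
    short <- want[[b]] - length(take)
    if (short > 0) {
      # borrow from the adjacent age bins of the same ethnicity; with
      # 5-year bins this stays within the design's age-matching width
      e <- sub(":[^:]*$", "", b)
      a <- as.numeric(sub("^.*:", "", b))
      near <- which(!used & ctrl_eth == e & abs(ctrl_age - a) == 1)
      near <- setdiff(near, take)
      extra <- utils::head(near[sample.int(length(near))], short)
      if (length(extra) < short)
        stop("matching infeasible: bin '", b, "' needs ", want[[b]],
             " controls but the pool (including adjacent age bins) is ",
             "short; increase pool_mult")
      take <- c(take, extra)
    }
    used[take] <- TRUE
    controls <- c(controls, ctrl_pool[take])
  }

  sel <- c(cases, controls)
  ids <- sprintf("S%05d", seq_along(sel))
  calls <- cbind(G[sel, , drop = FALSE],
                 if (!is.null(A)) A[sel, , drop = FALSE])
  if (config$missing_rate > 0) {
    drop_mask <- matrix(stats::runif(length(calls)) < config$missing_rate,
                        nrow(calls))
    calls[drop_mask] <- NA
  }
  samples <- data.frame(sample_id = ids,
                        status = rep(c(1, 0), c(length(cases),
                                                length(controls))),
                        age = age[sel], institution = inst[sel],
                        ethnicity = eth[sel], stringsAsFactors = FALSE)
  annot_used <- rbind(snp, aims)
  list(genotypes = genotype_matrix(calls, ids, colnames(calls)),
       samples = samples, annotation = annot_used, pop_freqs = pf)
}

#' Simulate a genotype matrix with planted quality-control violations
#'
#' Builds a 330-SNP fixture in which 320 SNPs satisfy the QC rules by
#' construction and 10 planted violators break exactly one rule each: four
#' with call rate below 0.90, three with minor allele frequency below 0.01 in
#' both ethnicity groups, and three deviating from Hardy-Weinberg proportions
#' (P < 0.01) in both groups. Clean SNPs are redrawn until they pass all
#' rules, so the expected exclusion set is exact.
#'
#' @param seed Integer seed.
#' @param n_samples Cohort size (default 600, two equal ethnicity groups).
#' @param n_clean,n_bad_cr,n_bad_maf,n_bad_hwe Counts per category.
#' @return List with `genotypes`, `samples`, and `planted` (data frame
#'   `snp_id`, `type` of the intended violation).
#' @export
simulate_qc_fixture <- function(seed, n_samples = 600, n_clean = 320,
                                n_bad_cr = 4, n_bad_maf = 3, n_bad_hwe = 3) {
  set.seed(seed)
  eth <- rep(c("group1", "group2"), length.out = n_samples)
  groups <- split(seq_len(n_samples), eth)
  rules_ok <- function(col) {
    if (mean(!is.na(col)) < 0.90) return(FALSE)
    hwe <- vapply(groups, function(i)
      hwe_chisq(.geno_counts(col[i]))$p_value, numeric(1))
    if (all(hwe < 0.01)) return(FALSE)
    mafs <- vapply(groups, function(i) compute_maf(col[i]), numeric(1))
    !all(mafs < 0.01)
  }
  draw_clean <- function() {
    repeat {
      f <- stats::runif(1, 0.10, 0.50)
      col <- stats::rbinom(n_samples, 2, f)
      if (rules_ok(col)) return(col)
    }
  }
  cols <- list()
  planted <- data.frame(snp_id = character(0), type = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_clean))
    cols[[sprintf("clean%03d", i)]] <- draw_clean()
  for (i in seq_len(n_bad_cr)) {
    repeat {
      col <- draw_clean()
      col[sample(n_samples, round(0.15 * n_samples))] <- NA
      if (!rules_ok(col) && mean(!is.na(col)) < 0.90) break
    }
    id <- sprintf("bad_cr%02d", i)
    cols[[id]] <- col
    planted <- rbind(planted, data.frame(snp_id = id, type = "call_rate"))
  }
  for (i in seq_len(n_bad_maf)) {
    col <- rep(0, n_samples)
    col[sample(groups[[1]], 1)] <- 1        # one heterozygote: MAF < 0.01
    id <- sprintf("bad_maf%02d", i)
    cols[[id]] <- col
    planted <- rbind(planted, data.frame(snp_id = id, type = "maf"))
  }
  for (i in seq_len(n_bad_hwe)) {
    col <- rep(1, n_samples)                # all heterozygous: HWE fails
    id <- sprintf("bad_hwe%02d", i)
    cols[[id]] <- col
    planted <- rbind(planted, data.frame(snp_id = id, type = "hwe"))
  }
  m <- do.call(cbind, cols)
  m <- m[, sample(ncol(m)), drop = FALSE]   # scatter violators
  ids <- sprintf("Q%04d", seq_len(n_samples))
  samples <- data.frame(sample_id = ids,
                        status = rep(c(0, 1), length.out = n_samples),
                        age = round(.sim_ages(n_samples, 65.9, 8.4,
                                              c(40, 90)), 1),
                        institution = "site1", ethnicity = eth,
                        stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(m, ids, colnames(m)),
       samples = samples, planted = planted)
}
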