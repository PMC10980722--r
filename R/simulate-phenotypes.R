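#' Simulate ASQ questionnaires
#'
#' Draws 50 binary item responses per subject from a two-parameter logistic
#' item-response model on a standard-normal latent autistic trait, with a
#' common discrimination and a spread of item difficulties calibrated (by
#' quadrature, deterministically) so the population of total scores matches
#' the target mean and SD. The total score is the item sum and lies in
#' 0--50, higher meaning more autistic traits.
#'
#' @param n Number of subjects (>= 1).
#' @param latent_mean_sd Length-2 numeric: target population mean and SD of
#'   the total score (defaults 21.4 and 5.6).
#' @param seed Optional integer seed (the global RNG state is preserved).
#'
#' @return A tibble with `subject_id`, `latent_trait` (standard-normal
#'   scale), `items` (list-column of 50 binary responses), and `asq_total`.
#' @export
#' @examples
#' ph <- simulate_asq_responses(5, seed = 1)
#' ph$asq_total
simulate_asq_responses <- function(n, latent_mean_sd = c(21.4, 5.6),
                                   seed = NULL) {
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  if (latent_mean_sd[2] < 0) stop("target SD must be nonnegative")
  n <- as.integer(n)
  par <- asq_item_parameters(latent_mean_sd[1], latent_mean_sd[2])
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  z <- stats::rnorm(n)
  prob <- stats::plogis(outer(z, par$difficulty, function(zi, bj)
    par$discrimination * (zi - bj)))
  item_mat <- matrix(stats::rbinom(length(prob), 1, prob), nrow = n)
  totals <- asq_total(item_mat)
  tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    latent_trait = z,
    items = lapply(seq_len(n), function(i) item_mat[i, ]),
    asq_total = totals
  )
}

#' Score ASQ response sheets
#'
#' @param items Binary matrix (subjects x 50 items) or a single length-50
#'   vector.
#' @return Integer total score(s), the row sums; range 0--50.
#' @export
asq_total <- function(items) {
  items <- rbind(items)
  if (ncol(items) != 50) stop("an ASQ sheet has 50 items")
  if (!all(items %in% c(0, 1))) stop("item responses must be binary")
  as.integer(rowSums(items))
}

# Calibrate the common discrimination and difficulty offset of the 50-item
# 2PL model so that total scores have the requested marginal mean and SD.
# Deterministic: Gaussian quadrature over the latent trait, Nelder-Mead on
# the two free parameters; cached per target.
asq_item_parameters <- function(target_mean, target_sd) {
  key <- paste(format(target_mean, digits = 12),
               format(target_sd, digits = 12))
  if (!is.null(.traitscan_cache[[key]])) return(.traitscan_cache[[key]])
  qd <- qnorm((seq_len(50) - 0.5) / 50)           # difficulty spread shape
  z <- seq(-6, 6, length.out = 401)
  w <- stats::dnorm(z); w <- w / sum(w)
  moments <- function(par) {
    a <- exp(par[1]); b0 <- par[2]
    p <- stats::plogis(a * outer(z, b0 + qd, `-`))  # nz x 50
    g <- rowSums(p)
    m <- sum(w * g)
    v <- sum(w * ((g - m)^2 + rowSums(p * (1 - p))))
    c(m, v)
  }
  obj <- function(par) {
    mv <- moments(par)
    (mv[1] - target_mean)^2 + (sqrt(mv[2]) - target_sd)^2
  }
  fit <- stats::optim(c(log(0.5), 0), obj, control = list(reltol = 1e-12,
                                                          maxit = 2000))
  out <- list(discrimination = exp(fit$par[1]),
              difficulty = fit$par[2] + qd)
  .traitscan_cache[[key]] <- out
  out
}

.traitscan_cache <- new.env(parent = emptyenv())

#' OXTR SNP panel
#'
#' The four oxytocin-receptor SNPs genotyped in the emulated study, their
#' allele pairs, the risk allele defining the dominant carrier grouping
#' (A+/T+ vs A-/T-), and plausible default risk-allele frequencies.
#'
#' @return A tibble with columns `snp`, `risk_allele`, `other_allele`,
#'   `risk_freq`.
#' @export
oxtr_snps <- function() {
  tibble::tibble(
    snp = c("rs2254298", "rs2268491", "rs2268498", "rs53576"),
    risk_allele = c("A", "T", "T", "A"),
    other_allele = c("G", "C", "C", "G"),
    risk_freq = c(0.3, 0.25, 0.45, 0.6)
  )
}

#' Simulate genotypes at Hardy-Weinberg equilibrium
#'
#' Genotypes are drawn per SNP with HWE proportions p^2, 2pq, q^2 for the
#' risk allele at frequency p; `carrier_<snp>` is 1 iff the subject carries
#' at least one risk allele (dominant grouping).
#'
#' @param n Number of subjects.
#' @param allele_freqs Named vector of risk-allele frequencies in (0, 1);
#'   default the [oxtr_snps()] panel.
#' @param risk_alleles Named character vector of risk alleles per SNP.
#' @param seed Optional integer seed.
#'
#' @return A tibble with `subject_id` and, per SNP, `genotype_<snp>`
#'   (unordered allele pair, risk allele first) and `carrier_<snp>` (0/1).
#' @export
simulate_genotypes <- function(n,
                               allele_freqs = NULL,
                               risk_alleles = NULL,
                               seed = NULL) {
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  panel <- oxtr_snps()
  if (is.null(allele_freqs))
    allele_freqs <- stats::setNames(panel$risk_freq, panel$snp)
  if (is.null(risk_alleles))
    risk_alleles <- stats::setNames(panel$risk_allele, panel$snp)
  if (any(allele_freqs <= 0) || any(allele_freqs > 1))
    stop("allele frequencies must lie in (0, 1]")
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  n <- as.integer(n)
  out <- tibble::tibble(subject_id = sprintf("sub-%03d", seq_len(n)))
  for (snp in names(allele_freqs)) {
    p <- allele_freqs[[snp]]
    risk <- risk_alleles[[snp]]
    other <- panel$other_allele[match(snp, panel$snp)]
    if (is.na(other)) other <- setdiff(c("A", "C", "G", "T"), risk)[1]
    n_risk <- stats::rbinom(n, 2, p)                 # HWE: binomial alleles
    geno <- c(paste0(other, other), paste0(risk, other),
              paste0(risk, risk))[n_risk + 1]
    out[[paste0("genotype_", snp)]] <- geno
    out[[paste0("carrier_", snp)]] <- as.integer(n_risk >= 1)
  }
  out
}

#' Simulate a full phenotype table
#'
#' Combines ASQ questionnaires, OXTR genotypes and demographics into the
#' per-subject table used as the decoding target and moderation covariates.
#'
#' @param n Number of subjects.
#' @param asq_mean_sd Target mean/SD of ASQ totals.
#' @param seed Integer seed.
#' @inheritParams simulate_genotypes
#' @return A tibble with ASQ, genotype, carrier, `sex` and `age` columns.
#' @export
simulate_phenotypes <- function(n, asq_mean_sd = c(21.4, 5.6),
                                allele_freqs = NULL, risk_alleles = NULL,
                                seed = 1L) {
  seed <- as.integer(seed)
  ph <- simulate_asq_responses(n, asq_mean_sd, seed = seed)
  gt <- simulate_genotypes(n, allele_freqs, risk_alleles, seed = seed + 1L)
  demo <- withr::with_seed(seed + 2L, tibble::tibble(
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(131, 124) / 255),
    age = pmin(pmax(round(stats::rnorm(n, 21.6, 2.3)), 17L), 29L)
  ))
  dplyr::bind_cols(ph, gt[-1], demo)
}
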