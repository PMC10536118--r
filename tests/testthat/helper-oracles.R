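# Independent brute-force oracles and small fixture builders.

## Exact two-tailed signed-rank p by full enumeration of sign assignments
## (midranks; zero differences dropped). Independent of the package's
## convolution implementation.
enum_signed_rank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  stats <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  lo <- mean(stats <= W)
  hi <- mean(stats >= W)
  min(1, 2 * min(lo, hi))
}

## Exact two-tailed Mann-Whitney p by enumeration of all group labelings.
enum_mwu_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  stats <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  lo <- mean(stats <= U_obs)
  hi <- mean(stats >= U_obs)
  min(1, 2 * min(lo, hi))
}

## Hand application of the BH step-up transform.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

## Minimal two-metabolite plasma table builder.
tiny_table <- function(ab, dose = NULL, role = NULL, tissue = "plasma",
                       day = 1, animal = NULL, weight = NA_real_,
                       is_channel = NA_character_, chem_class = "other",
                       acyl_chain = NA_character_) {
  n <- nrow(ab); p <- ncol(ab)
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("s%02d", seq_len(n))
  if (is.null(colnames(ab))) colnames(ab) <- sprintf("m%02d", seq_len(p))
  if (is.null(dose)) dose <- rep(0, n)
  if (is.null(role)) role <- rep("study", n)
  if (is.null(animal)) animal <- sprintf("a%02d", seq_len(n))
  SampleTable(ab,
    samples = data.frame(sample_id = rownames(ab), animal_id = animal,
                         tissue = tissue, dose_gy = dose, day = day,
                         role = role, tissue_weight_mg = weight,
                         stringsAsFactors = FALSE),
    metabolites = data.frame(metabolite_id = colnames(ab),
                             name = colnames(ab),
                             chem_class = chem_class,
                             acyl_chain = acyl_chain,
                             is_channel = is_channel,
                             stringsAsFactors = FALSE))
}

## A small but complete simulated cohort for pipeline-level tests.
small_config <- function(seed = 1, ...) {
  simConfig(n_metabolites = 20, n_planted = 7, seed = seed, ...)
}
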