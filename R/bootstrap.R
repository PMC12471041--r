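# Per-individual summaries used by the vectorised bootstrap: alive-by-age
# and eggs-by-age indicator matrices plus the scalar contributions of each
# individual to every reported parameter.
.cohort_arrays <- function(x) {
  rec <- x$records
  n <- x$n
  seqs <- .stage_seqs(x)
  ls <- lengths(seqs)
  X <- max(ls)
  alive <- matrix(0, n, X)
  alive[cbind(rep(seq_len(n), ls),
              unlist(lapply(ls, seq_len), use.names = FALSE))] <- 1
  eggs <- matrix(0, n, X)
  fec <- x$fecundity
  if (nrow(fec)) {
    la <- .laying_age(x)  # 0-based ages
    i <- match(fec$id, rec$id)
    for (k in seq_along(i)) {
      eggs[i[k], la[k] + 1L] <- eggs[i[k], la[k] + 1L] + fec$eggs[k]
    }
  }
  emerged <- rec$death_stage == "adult"
  female <- rec$sex == "female"
  total_eggs <- as.numeric(rowSums(eggs))
  pos <- fec[fec$eggs > 0, , drop = FALSE]
  repf <- female & rec$id %in% pos$id
  first_day <- rep(NA_real_, n)
  ovi <- rep(0, n)
  if (nrow(pos)) {
    fd <- tapply(pos$adult_day, pos$id, min)
    od <- tapply(pos$adult_day, pos$id, length)
    idx <- match(names(fd), rec$id)
    first_day[idx] <- as.numeric(fd)
    ovi[idx] <- as.numeric(od)
  }
  emerg_age <- rec$egg_d + rec$larva_d + rec$pupa_d  # NA for non-emergers
  comp_egg <- rec$death_stage != "egg"
  comp_larva <- rec$death_stage %in% c("pupa", "adult")
  comp_pupa <- emerged
  z <- function(v, keep) ifelse(keep & !is.na(v), v, 0)
  list(
    n = n, X = X, alive = alive, eggs = eggs,
    emerged = as.numeric(emerged), female = as.numeric(female),
    male = as.numeric(rec$sex == "male"), repf = as.numeric(repf),
    total_eggs = total_eggs,
    apop = z(first_day - 1, repf), tpop = z(emerg_age + first_day - 1, repf),
    ovi = z(ovi, repf),
    egg_c = as.numeric(comp_egg), egg_dur = z(rec$egg_d, comp_egg),
    larva_c = as.numeric(comp_larva), larva_dur = z(rec$larva_d, comp_larva),
    pupa_c = as.numeric(comp_pupa), pupa_dur = z(rec$pupa_d, comp_pupa),
    adult_dur = z(rec$adult_longevity_d, emerged),
    preadult_dur = z(emerg_age, emerged)
  )
}

.BOOT_PARAMS <- c("r", "lambda", "T", "R0", "GRR", "F", "Fn", "RepF",
                  "male_count", "Sa", "female_fraction", "APOP", "TPOP",
                  "ovi_days", "egg_days", "larva_days", "pupa_days",
                  "adult_days", "preadult_days")

# Compute the full parameter set for `bc` resamples encoded as a count
# matrix W (bc x n, row sums = n).
.boot_chunk <- function(W, a) {
  n <- a$n
  bc <- nrow(W)
  A <- W %*% a$alive           # alive counts by age
  E <- W %*% a$eggs            # eggs laid by age
  lxmx <- E / n
  R0 <- rowSums(lxmx)
  mx <- E / A
  mx[A == 0] <- 0
  GRR <- rowSums(mx)
  r <- .solve_r_vec(lxmx)
  lambda <- exp(r)
  Tgen <- rep(NA_real_, bc)
  pos <- is.finite(r)
  near0 <- pos & abs(r) < 1e-9
  Tgen[pos & !near0] <- log(R0[pos & !near0]) / r[pos & !near0]
  if (any(near0)) {
    xw <- lxmx %*% (seq_len(ncol(lxmx)) - 1)
    Tgen[near0] <- xw[near0] / R0[near0]
  }
  sums <- W %*% cbind(a$emerged, a$female, a$male, a$repf, a$total_eggs,
                      a$apop, a$tpop, a$ovi,
                      a$egg_c, a$egg_dur, a$larva_c, a$larva_dur,
                      a$pupa_c, a$pupa_dur, a$adult_dur, a$preadult_dur)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  Fn <- sums[, 2]
  repf <- sums[, 4]
  cbind(
    r = r, lambda = lambda, T = Tgen, R0 = R0, GRR = GRR,
    F = ratio(sums[, 5], Fn),
    Fn = Fn, RepF = repf, male_count = sums[, 3],
    Sa = sums[, 1] / n, female_fraction = Fn / n,
    APOP = ratio(sums[, 6], repf), TPOP = ratio(sums[, 7], repf),
    ovi_days = ratio(sums[, 8], repf),
    egg_days = ratio(sums[, 10], sums[, 9]),
    larva_days = ratio(sums[, 12], sums[, 11]),
    pupa_days = ratio(sums[, 14], sums[, 13]),
    adult_days = ratio(sums[, 15], sums[, 1]),
    preadult_days = ratio(sums[, 16], sums[, 1])
  )
}

#' Individual-resampling bootstrap of all life-table parameters
#'
#' Each replicate resamples the cohort's n individuals with replacement --
#' the resampling unit is the whole individual with its complete life
#' history and fecundity schedule -- and recomputes every life-table
#' parameter. The reported SE is the standard deviation of the bootstrap
#' distribution; 95% percentile confidence limits are reported alongside.
#' Replicates where a parameter is undefined (e.g. r, lambda, T when the
#' resample contains no reproducing female, so R0 = 0; or APOP when no
#' reproductive female was drawn) are excluded from that parameter's
#' aggregation, and the number of valid replicates is reported.
#' Deterministic given (cohort, B, seed): replicates are generated from one
#' seeded stream in fixed-size blocks, so the same inputs always reproduce
#' identical results.
#'
#' @param x a [cohort].
#' @param B number of bootstrap replicates (>= 1). The conventional count
#'   for published tables is 100,000.
#' @param seed integer random seed; mandatory.
#' @param conf level for the percentile interval (default 0.95).
#' @param keep_draws attach the full B x parameter draw matrix as the
#'   `"draws"` attribute (default TRUE; needed by [bootstrap_diff()]).
#' @return An object of class `"bootstrap_result"`: a data.frame with
#'   columns `parameter`, `mean`, `SE`, `CI_lo`, `CI_hi`, `valid_B`, `B`,
#'   `seed`.
#' @export
bootstrap_lifetable <- function(x, B, seed, conf = 0.95, keep_draws = TRUE) {
  stopifnot(inherits(x, "cohort"))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  B <- as.integer(B)
  if (is.na(B) || B < 1) stop("B must be a positive integer")
  a <- .cohort_arrays(x)
  set.seed(as.integer(seed))
  chunk <- 10000L
  draws <- matrix(NA_real_, B, length(.BOOT_PARAMS),
                  dimnames = list(NULL, .BOOT_PARAMS))
  done <- 0L
  while (done < B) {
    bc <- min(chunk, B - done)
    idx <- sample.int(a$n, bc * a$n, replace = TRUE)
    W <- matrix(tabulate(rep(seq_len(bc), each = a$n) + (idx - 1L) * bc,
                         nbins = bc * a$n), nrow = bc, ncol = a$n)
    draws[(done + 1L):(done + bc), ] <- .boot_chunk(W, a)
    done <- done + bc
  }
  alpha <- (1 - conf) / 2
  res <- data.frame(
    parameter = .BOOT_PARAMS,
    mean = apply(draws, 2, mean, na.rm = TRUE),
    SE = apply(draws, 2, stats::sd, na.rm = TRUE),
    CI_lo = apply(draws, 2, stats::quantile, probs = alpha, na.rm = TRUE,
                  names = FALSE),
    CI_hi = apply(draws, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE,
                  names = FALSE),
    valid_B = apply(draws, 2, function(v) sum(!is.na(v))),
    B = B, seed = as.integer(seed), row.names = NULL
  )
  # single-valued distributions have SE 0, not NA
  res$SE[res$valid_B == 1] <- 0
  class(res) <- c("bootstrap_result", "data.frame")
  if (keep_draws) attr(res, "draws") <- draws
  res
}

#' Paired bootstrap differences between two cohorts
#'
#' Bootstraps both cohorts with the same seed and replicate count and
#' summarises the per-replicate parameter differences (A - B): mean, SE
#' (bootstrap SD of the difference) and the percentile interval. With the
#' same seed the replicate index streams are shared, so comparing a cohort
#' against itself gives exactly zero difference in every replicate.
#'
#' @param cohortA,cohortB two [cohort] objects.
#' @param B replicate count.
#' @param seed integer random seed; mandatory.
#' @param conf percentile interval level.
#' @return data.frame `parameter, diff_mean, diff_SE, CI_lo, CI_hi,
#'   valid_B, B, seed` of class `"bootstrap_diff"`.
#' @export
bootstrap_diff <- function(cohortA, cohortB, B, seed, conf = 0.95) {
  ra <- bootstrap_lifetable(cohortA, B, seed, conf)
  rb <- bootstrap_lifetable(cohortB, B, seed, conf)
  d <- attr(ra, "draws") - attr(rb, "draws")
  alpha <- (1 - conf) / 2
  out <- data.frame(
    parameter = .BOOT_PARAMS,
    diff_mean = apply(d, 2, mean, na.rm = TRUE),
    diff_SE = apply(d, 2, stats::sd, na.rm = TRUE),
    CI_lo = apply(d, 2, stats::quantile, probs = alpha, na.rm = TRUE,
                  names = FALSE),
    CI_hi = apply(d, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE,
                  names = FALSE),
    valid_B = apply(d, 2, function(v) sum(!is.na(v))),
    B = as.integer(B), seed = as.integer(seed), row.names = NULL
  )
  class(out) <- c("bootstrap_diff", "data.frame")
  out
}

#' Write a bootstrap summary as TSV
#' @param res a `"bootstrap_result"` or `"bootstrap_diff"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bootstrap <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
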