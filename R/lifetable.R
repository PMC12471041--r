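#' Age-stage-specific survival rates
#'
#' Computes the matrix s_xj: the proportion of the initial cohort alive and
#' in stage j on age-day x, with age 0 the day of oviposition and the adult
#' stage split by sex (stages: egg, larva, pupa, female adult, male adult).
#' An individual is assigned to the later stage on a transition day
#' (half-open day convention): with egg_d = 3 it is in the egg stage on ages
#' 0, 1, 2 and a larva on age 3.
#'
#' @param x a [cohort].
#' @return An object of class `"agestage_matrix"`: a numeric matrix with one
#'   row per age (rownames `0..x_max`) and one column per stage, with
#'   attributes `n` (cohort size) and `counts` (the underlying integer
#'   roll-call counts).
#' @export
compute_sxj <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (x$n < 1) stop("empty cohort")
  seqs <- .stage_seqs(x)
  xmax <- max(lengths(seqs)) - 1L
  m <- length(STAGES)
  day <- unlist(lapply(seqs, seq_along), use.names = FALSE)
  stage <- unlist(seqs, use.names = FALSE)
  counts <- matrix(tabulate(day + (stage - 1L) * (xmax + 1L),
                            nbins = (xmax + 1L) * m),
                   nrow = xmax + 1L, ncol = m,
                   dimnames = list(0:xmax, STAGES))
  out <- counts / x$n
  attr(out, "n") <- x$n
  attr(out, "counts") <- counts
  class(out) <- c("agestage_matrix", "matrix")
  out
}

#' Age-specific survival rate
#'
#' l_x = sum over stages j of s_xj: the probability that a newborn is alive
#' at age x, both sexes and all stages pooled.
#'
#' @param S an `"agestage_matrix"` from [compute_sxj()].
#' @return numeric vector l_x, names `0..x_max`.
#' @export
compute_lx <- function(S) {
  stopifnot(inherits(S, "agestage_matrix"))
  rowSums(unclass(S))
}

#' Age-specific fecundity schedules
#'
#' Builds the life-table curves from the age-stage survival matrix and the
#' cohort's daily egg counts. The female-adult stage fecundity is
#' f_x,female = (eggs laid on age-day x) / (n * s_x,female), so that the
#' population schedule m_x = sum_j s_xj f_xj / sum_j s_xj and the net
#' maternity l_x m_x = (eggs laid at age x) / n. m_x is defined as 0 where
#' no one is alive.
#'
#' @param S an `"agestage_matrix"`.
#' @param x the [cohort] the matrix was computed from.
#' @return An object of class `"lifetable_curves"`: a data.frame with
#'   columns `x`, `lx`, `fx_female`, `mx`, `lxmx`.
#' @export
compute_mx <- function(S, x) {
  stopifnot(inherits(S, "agestage_matrix"), inherits(x, "cohort"))
  n <- attr(S, "n")
  ages <- as.integer(rownames(S))
  eggs <- numeric(length(ages))
  la <- .laying_age(x)
  if (length(la)) {
    tab <- tapply(x$fecundity$eggs, la, sum)
    idx <- match(as.integer(names(tab)), ages)
    if (anyNA(idx)) stop("egg laid at an age beyond the survival matrix")
    eggs[idx] <- as.numeric(tab)
  }
  sfem <- S[, "female"]
  fx <- ifelse(sfem > 0, eggs / (n * sfem), 0)
  lx <- compute_lx(S)
  mx <- ifelse(lx > 0, (eggs / n) / lx, 0)
  out <- data.frame(x = ages, lx = as.numeric(lx), fx_female = fx,
                    mx = mx, lxmx = lx * mx, row.names = NULL)
  class(out) <- c("lifetable_curves", "data.frame")
  out
}

#' Net and gross reproduction rates
#'
#' R0 = sum of l_x m_x (mean lifetime offspring per newborn);
#' GRR = sum of m_x (reproduction if mortality were absent).
#'
#' @param curves a `"lifetable_curves"` object.
#' @return named numeric vector `c(R0 = , GRR = )`.
#' @export
compute_R0_GRR <- function(curves) {
  stopifnot(inherits(curves, "lifetable_curves"))
  c(R0 = sum(curves$lxmx), GRR = sum(curves$mx))
}

# Vectorised Euler-Lotka residual: rows of `lxmx` are schedules over ages
# 0..X-1; residual(r) = sum_x exp(-r (x+1)) lxmx - 1, decreasing in r.
.el_residual <- function(r, lxmx, tt) {
  ex <- exp(pmin(-outer(r, tt), 700))
  rowSums(ex * lxmx) - 1
}

# Vectorised bisection for the Euler-Lotka root; returns NA where R0 == 0.
.solve_r_vec <- function(lxmx) {
  lxmx <- rbind(lxmx)
  tt <- seq_len(ncol(lxmx))  # exponent uses age + 1
  R0 <- rowSums(lxmx)
  r <- rep(NA_real_, nrow(lxmx))
  ok <- R0 > 0
  if (!any(ok)) return(r)
  m <- lxmx[ok, , drop = FALSE]
  lo <- rep(-1, nrow(m)); hi <- rep(2, nrow(m))
  # expand brackets for extreme schedules
  for (k in 1:40) {
    bad <- .el_residual(lo, m, tt) < 0
    if (!any(bad)) break
    lo[bad] <- lo[bad] * 2
  }
  for (k in 1:40) {
    bad <- .el_residual(hi, m, tt) > 0
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2
  }
  for (k in 1:100) {
    mid <- (lo + hi) / 2
    res <- .el_residual(mid, m, tt)
    up <- res > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  r[ok] <- (lo + hi) / 2
  r
}

#' Solve the Euler-Lotka equation for the population growth parameters
#'
#' Finds the intrinsic rate of increase r as the unique real root of
#' sum_x exp(-r (x+1)) l_x m_x = 1 (age indexed from 0, exponent x+1), by
#' bisection with a Newton polish, then derives the finite rate lambda =
#' exp(r) and the mean generation time T = ln(R0)/r. When R0 = 1 (r = 0),
#' T is reported as sum(x * lxmx)/R0, the limit convention, and flagged.
#' When R0 = 0 the growth parameters are undefined and flagged.
#'
#' @param curves a `"lifetable_curves"` object.
#' @return An object of class `"population_parameters"`: list with `r`,
#'   `lambda`, `R0`, `GRR`, `T`, the Euler-Lotka `residual` at the root and
#'   a character vector of `flags`.
#' @export
solve_r <- function(curves) {
  stopifnot(inherits(curves, "lifetable_curves"))
  rg <- compute_R0_GRR(curves)
  R0 <- rg[["R0"]]
  flags <- character()
  if (R0 <= 0) {
    out <- list(r = NA_real_, lambda = NA_real_, R0 = R0, GRR = rg[["GRR"]],
                T = NA_real_, residual = NA_real_,
                flags = "undefined: no reproduction (R0 = 0)")
    class(out) <- "population_parameters"
    return(out)
  }
  lxmx <- curves$lxmx
  tt <- curves$x + 1
  r <- .solve_r_vec(matrix(lxmx, nrow = 1))[1]
  # Newton polish on the residual
  for (k in 1:5) {
    res <- sum(exp(-r * tt) * lxmx) - 1
    dres <- -sum(tt * exp(-r * tt) * lxmx)
    step <- res / dres
    if (!is.finite(step)) break
    r <- r - step
    if (abs(step) < 1e-15) break
  }
  residual <- sum(exp(-r * tt) * lxmx) - 1
  if (abs(r) < 1e-9) {
    Tgen <- sum(curves$x * lxmx) / R0
    flags <- c(flags, "R0 = 1: r = 0, T reported by limit convention")
  } else {
    Tgen <- log(R0) / r
  }
  out <- list(r = r, lambda = exp(r), R0 = R0, GRR = rg[["GRR"]],
              T = Tgen, residual = residual, flags = flags)
  class(out) <- "population_parameters"
  out
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("Population growth parameters (daily time step):\n")
  cat(sprintf("  r = %.5f /d   lambda = %.5f /d   R0 = %.4f   GRR = %.4f   T = %.4f d\n",
              x$r, x$lambda, x$R0, x$GRR, x$T))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Daily age-stage transition structure of a cohort: occupancy counts N[x, j]
# and transition counts TR[x, j, y] from (age x, stage j) to (age x+1,
# stage y), with y = 6 meaning death before the next census.
.transitions <- function(x) {
  seqs <- .stage_seqs(x)
  xmax <- max(lengths(seqs)) - 1L
  m <- length(STAGES)
  X <- xmax + 1L
  day <- unlist(lapply(seqs, seq_along), use.names = FALSE)
  stage <- unlist(seqs, use.names = FALSE)
  to <- unlist(lapply(seqs, function(s) c(s[-1], m + 1L)), use.names = FALSE)
  N <- matrix(tabulate(day + (stage - 1L) * X, nbins = X * m),
              nrow = X, ncol = m, dimnames = list(0:xmax, STAGES))
  TR <- array(tabulate(day + (stage - 1L) * X + (to - 1L) * X * m,
                       nbins = X * m * (m + 1L)),
              dim = c(X, m, m + 1L),
              dimnames = list(0:xmax, STAGES, c(STAGES, "dead")))
  list(N = N, TR = TR, xmax = xmax)
}

# Propagate a hypothetical cohort placed with mass 1 at (x0, j0) through the
# empirical daily transition probabilities; returns the mass matrix s' over
# ages x0..xmax and all stages.
.propagate <- function(tr, x0, j0) {
  m <- length(STAGES)
  rows <- tr$xmax - x0 + 1L
  mass <- matrix(0, rows, m, dimnames = list(x0:tr$xmax, STAGES))
  mass[1, j0] <- 1
  if (rows > 1) {
    for (i in seq_len(rows - 1L)) {
      age <- x0 + i - 1L
      cur <- mass[i, ]
      for (j in which(cur > 0)) {
        Nj <- tr$N[age + 1L, j]
        if (Nj > 0) {
          p <- tr$TR[age + 1L, j, 1:m] / Nj
          mass[i + 1L, ] <- mass[i + 1L, ] + cur[j] * p
        }
      }
    }
  }
  mass
}

#' Age-stage life expectancy
#'
#' Expected remaining days of life for an individual of age x in stage j,
#' computed by the hypothetical-cohort construction: a unit of survival is
#' placed at (x, j) and propagated forward with the cohort's empirical daily
#' stage-transition and survival probabilities; e_xj is the total mass
#' summed over all later ages and stages. Under the day-counting convention
#' the occupant's current day counts, so e_xj >= 1 for every occupied cell,
#' and e at age 0 in the egg stage equals the cohort mean lifespan. Cells
#' never occupied in the observed cohort are `NA`.
#'
#' The printed source formulas for this quantity are followed in the
#' standard age-stage (two-sex) hypothetical-cohort form; see the package
#' vignette for the convention.
#'
#' @param x a [cohort].
#' @return An object of class `"stage_expectancy"`: a numeric matrix e_xj
#'   (ages x stages) with attribute `convention`.
#' @export
life_expectancy <- function(x) {
  stopifnot(inherits(x, "cohort"))
  tr <- .transitions(x)
  m <- length(STAGES)
  e <- matrix(NA_real_, tr$xmax + 1L, m, dimnames = list(0:tr$xmax, STAGES))
  for (age in 0:tr$xmax) {
    for (j in seq_len(m)) {
      if (tr$N[age + 1L, j] > 0) {
        e[age + 1L, j] <- sum(.propagate(tr, age, j))
      }
    }
  }
  attr(e, "convention") <- "hypothetical cohort, empirical daily transitions"
  class(e) <- c("stage_expectancy", "matrix")
  e
}

# Empirical per-capita daily fecundity of each (age, stage) cell: eggs laid
# at age x by stage-j occupants divided by the occupant count. Nonzero only
# for the female-adult stage.
.cell_fecundity <- function(x, tr) {
  m <- length(STAGES)
  f <- matrix(0, tr$xmax + 1L, m, dimnames = list(0:tr$xmax, STAGES))
  la <- .laying_age(x)
  if (length(la)) {
    tab <- tapply(x$fecundity$eggs, la, sum)
    ages <- as.integer(names(tab))
    f[cbind(ages + 1L, 4L)] <- as.numeric(tab) / tr$N[cbind(ages + 1L, 4L)]
  }
  f
}

#' Age-stage reproductive value
#'
#' v_xj: the expected contribution of an individual of age x in stage j to
#' future population growth, i.e. its expected future offspring discounted
#' at the intrinsic rate r. Computed with the same hypothetical cohort as
#' [life_expectancy()]: v_xj = exp(r (x+1)) * sum over i >= x of
#' exp(-r (i+1)) * sum over stages y of s'_iy f'_iy, where s' is the
#' propagated unit mass from (x, j) and f' the empirical per-capita cell
#' fecundity. Male-adult cells have v = 0 at every age; unoccupied cells
#' are `NA`. Requires a finite r (R0 > 0).
#'
#' @param x a [cohort].
#' @param params a `"population_parameters"` object for the same cohort
#'   (for the discount rate r); computed if omitted.
#' @return An object of class `"reproductive_value"`: matrix v_xj with
#'   attribute `r`.
#' @export
reproductive_value <- function(x, params = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(params)) {
    params <- solve_r(compute_mx(S <- compute_sxj(x), x))
  }
  r <- params$r
  if (!is.finite(r)) stop("reproductive value undefined: r is not finite (R0 = 0)")
  tr <- .transitions(x)
  m <- length(STAGES)
  f <- .cell_fecundity(x, tr)
  v <- matrix(NA_real_, tr$xmax + 1L, m, dimnames = list(0:tr$xmax, STAGES))
  for (age in 0:tr$xmax) {
    for (j in seq_len(m)) {
      if (tr$N[age + 1L, j] > 0) {
        if (j == 5L) { v[age + 1L, j] <- 0; next }  # males contribute no eggs
        mass <- .propagate(tr, age, j)
        ii <- age:tr$xmax
        disc <- exp(-r * (ii + 1))
        v[age + 1L, j] <- exp(r * (age + 1)) *
          sum(disc * rowSums(mass * f[ii + 1L, , drop = FALSE]))
      }
    }
  }
  attr(v, "r") <- r
  class(v) <- c("reproductive_value", "matrix")
  v
}

#' Reproductive and survivorship summary of a cohort
#'
#' Cohort-level bookkeeping matching the conventional reporting of two-sex
#' life-table studies: counts of emerged females (Fn), reproductive females
#' (RepF, females laying at least one egg) and males; the adult
#' pre-oviposition period APOP (days from emergence to first laying, mean
#' over reproductive females); the total pre-oviposition period TPOP (age
#' at first laying, from age 0 = oviposition day); preadult survivorship
#' Sa = emerged adults / n; mean oviposition days (days with >= 1 egg);
#' mean eggs per emerged female F; and the female fraction Fn/n.
#'
#' @param x a [cohort].
#' @return An object of class `"reproduction_summary"` (a list). APOP,
#'   TPOP and oviposition days are `NA` with a flag when no female
#'   reproduced.
#' @export
summarize_reproduction <- function(x) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  fec <- x$fecundity[x$fecundity$eggs > 0, , drop = FALSE]
  females <- rec$id[rec$sex == "female"]
  repf <- intersect(females, unique(fec$id))
  flags <- character()
  if (length(repf)) {
    first_day <- tapply(fec$adult_day, fec$id, min)[repf]
    m <- match(repf, rec$id)
    emerg_age <- rec$egg_d[m] + rec$larva_d[m] + rec$pupa_d[m]
    apop <- mean(first_day - 1)
    tpop <- mean(emerg_age + first_day - 1)
    ovi <- mean(as.numeric(table(fec$id)[repf]))
  } else {
    apop <- tpop <- ovi <- NA_real_
    flags <- "no reproductive females: APOP/TPOP/ovi_days undefined"
  }
  Fn <- length(females)
  total_eggs <- sum(x$fecundity$eggs)
  out <- list(
    Fn = Fn,
    RepF = length(repf),
    male_count = sum(rec$sex == "male"),
    APOP = apop,
    TPOP = tpop,
    Sa = sum(rec$death_stage == "adult") / x$n,
    ovi_days = ovi,
    F = if (Fn > 0) total_eggs / Fn else NA_real_,
    female_fraction = Fn / x$n,
    total_eggs = total_eggs,
    n = x$n,
    flags = flags
  )
  class(out) <- "reproduction_summary"
  out
}

#' @export
print.reproduction_summary <- function(x, ...) {
  cat(sprintf("Reproduction summary (n = %d):\n", x$n))
  cat(sprintf("  Fn = %d  RepF = %d  males = %d  Sa = %.3f  female fraction = %.3f\n",
              x$Fn, x$RepF, x$male_count, x$Sa, x$female_fraction))
  cat(sprintf("  APOP = %.2f d  TPOP = %.2f d  ovi days = %.2f  F = %.2f eggs/female\n",
              x$APOP, x$TPOP, x$ovi_days, x$F))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Full age-stage two-sex life-table analysis of a cohort
#'
#' One-call wrapper running the whole engine: age-stage survival matrix,
#' survival/fecundity schedules, Euler-Lotka growth parameters, age-stage
#' life expectancy and reproductive value, and the reproductive summary.
#'
#' @param x a [cohort].
#' @param reproductive_values compute the v_xj matrix (requires R0 > 0;
#'   skipped automatically with a flag when the cohort has no reproduction).
#' @return An object of class `"lifetable"`: list with elements `sxj`,
#'   `curves`, `params`, `exj`, `vxj`, `summary`, `treatment`, `meta`.
#' @export
lifetable <- function(x, reproductive_values = TRUE) {
  stopifnot(inherits(x, "cohort"))
  S <- compute_sxj(x)
  curves <- compute_mx(S, x)
  params <- solve_r(curves)
  exj <- life_expectancy(x)
  vxj <- NULL
  if (reproductive_values && is.finite(params$r)) {
    vxj <- reproductive_value(x, params)
  }
  out <- list(
    sxj = S, curves = curves, params = params, exj = exj, vxj = vxj,
    summary = summarize_reproduction(x), treatment = x$treatment,
    meta = list(
      exj_vxj_convention = attr(exj, "convention"),
      census_interval_d = 1L
    )
  )
  class(out) <- "lifetable"
  out
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Age-stage two-sex life table — treatment", x$treatment, "\n")
  print(x$params)
  print(x$summary)
  invisible(x)
}

#' Write life-table results as round-trippable text tables
#'
#' Emits `curves.tsv` (`x,lx,mx,lxmx` plus female fecundity), `agestage.tsv`
#' (long-format `x,stage,sxj,exj,vxj`) and `params.json` into `dir`, with
#' the treatment label prefixed.
#'
#' @param lt a `"lifetable"`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; defaults to the treatment label.
#' @return character vector of the files written, invisibly.
#' @export
write_lifetable <- function(lt, dir, prefix = NULL) {
  stopifnot(inherits(lt, "lifetable"))
  if (is.null(prefix)) prefix <- paste0("trt", lt$treatment)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, paste0(prefix, "_curves.tsv"))
  utils::write.table(lt$curves, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  ages <- as.integer(rownames(lt$sxj))
  long <- do.call(rbind, lapply(seq_along(STAGES), function(j) {
    data.frame(x = ages, stage = STAGES[j], sxj = lt$sxj[, j],
               exj = lt$exj[, j],
               vxj = if (is.null(lt$vxj)) NA_real_ else lt$vxj[, j])
  }))
  f2 <- file.path(dir, paste0(prefix, "_agestage.tsv"))
  utils::write.table(long, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  f3 <- file.path(dir, paste0(prefix, "_params.json"))
  pj <- lt$params
  s <- lt$summary
  jsonlite::write_json(
    list(treatment = lt$treatment,
         r = pj$r, lambda = pj$lambda, R0 = pj$R0, GRR = pj$GRR, T = pj$T,
         euler_lotka_residual = pj$residual, flags = pj$flags,
         Fn = s$Fn, RepF = s$RepF, male_count = s$male_count,
         APOP = s$APOP, TPOP = s$TPOP, Sa = s$Sa, ovi_days = s$ovi_days,
         F = s$F, female_fraction = s$female_fraction, n = s$n,
         meta = lt$meta),
    f3, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(f1, f2, f3))
}
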