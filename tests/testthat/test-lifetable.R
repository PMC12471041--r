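test_that("age-stage survival rates match hand enumeration and brute force", {
  # n = 1, dies in the egg after 2 days
  S <- compute_sxj(cohort(death_rec("a", "egg", egg = 2)))
  expect_equal(unname(S[, "egg"]), c(1, 1))
  expect_equal(sum(S[, -1]), 0)
  # n = 2: one dies in egg on day 1, one lives egg 2 d / larva 3 d
  co <- cohort(rbind(death_rec("a", "egg", egg = 1),
                     death_rec("b", "larva", egg = 2, larva = 3)))
  S <- compute_sxj(co)
  expect_equal(unname(S["0", "egg"]), 1)
  expect_equal(unname(S["1", "egg"]), 0.5)
  expect_equal(unname(S["2", "larva"]), 0.5)
  expect_equal(unname(compute_lx(S)), c(1, 0.5, 0.5, 0.5, 0.5))
  # generated cohort against an independent day-by-day roll call
  co <- simulate_cohort(default_params("0", n = 200), seed = 31)
  expect_equal(unclass(compute_sxj(co))[, ], brute_force_sxj(co),
               ignore_attr = TRUE)
  # female plateau cannot exceed the female fraction
  expect_lte(max(compute_sxj(co)[, "female"]),
             summarize_reproduction(co)$female_fraction)
})

test_that("lx is non-increasing for arbitrary generated cohorts", {
  for (seed in 1:100) {
    trt <- c("0", "3", "30", "300")[(seed %% 4) + 1]
    co <- simulate_cohort(default_params(trt), seed = seed)
    lx <- compute_lx(compute_sxj(co))
    expect_true(all(diff(lx) <= 1e-12))
    expect_equal(unname(lx[1]), 1)
  }
})

test_that("age-specific fecundity pools stages and guards empty ages", {
  # 5 individuals: at the focal age 1 female + 1 male alive (s = 0.2 each),
  # female lays 10 eggs that day -> mx = (0.2 * 10) / 0.4 = 5
  rec <- rbind(adult_rec("f", "female", egg = 1, larva = 1, pupa = 1, longevity = 5),
               adult_rec("m", "male", egg = 1, larva = 1, pupa = 1, longevity = 5),
               death_rec("d1", "egg", egg = 1),
               death_rec("d2", "egg", egg = 1),
               death_rec("d3", "egg", egg = 1))
  co <- cohort(rec, data.frame(id = "f", adult_day = 2, eggs = 10))
  curves <- compute_mx(compute_sxj(co), co)
  at <- curves[curves$x == 4, ]  # adult day 2 = age 4
  expect_equal(at$lx, 0.4)
  expect_equal(at$mx, 5)
  expect_equal(at$fx_female, 10 / (5 * 0.2))
  # cohort with no females: mx is identically zero and R0 = 0
  co <- cohort(rbind(adult_rec("m1", "male"), adult_rec("m2", "male")))
  curves <- compute_mx(compute_sxj(co), co)
  expect_true(all(curves$mx == 0))
  expect_equal(unname(compute_R0_GRR(curves)["R0"]), 0)
  params <- solve_r(curves)
  expect_true(is.na(params$r))
  expect_match(params$flags, "R0 = 0")
})

test_that("the Euler-Lotka solver recovers closed-form roots", {
  mk <- function(lxmx) {
    out <- data.frame(x = seq_along(lxmx) - 1, lx = 1, fx_female = 0,
                      mx = lxmx, lxmx = lxmx)
    class(out) <- c("lifetable_curves", "data.frame")
    out
  }
  # all reproduction at age 0 with R0 = 1: exp(-r) = 1 => r = 0
  p <- solve_r(mk(c(1)))
  expect_equal(p$r, 0, tolerance = 1e-9)
  # R0 = 2 at age 1: 2 exp(-2r) = 1 => r = ln(2)/2
  p <- solve_r(mk(c(0, 2)))
  expect_equal(p$r, log(2) / 2, tolerance = 1e-10)
  expect_lt(abs(p$residual), 1e-10)
  # single-age reproduction closed form r = ln(R0)/(a + 1)
  for (R0 in c(0.5, 5, 93.7)) {
    for (a in c(3, 17)) {
      lxmx <- rep(0, a + 1); lxmx[a + 1] <- R0
      p <- solve_r(mk(lxmx))
      expect_equal(p$r, log(R0) / (a + 1), tolerance = 1e-10)
      expect_equal(p$T, a + 1, tolerance = 1e-8)
    }
  }
})

test_that("growth-parameter identities hold to machine precision", {
  for (seed in c(2, 13, 77)) {
    co <- simulate_cohort(default_params("0", n = 100), seed = seed)
    lt <- lifetable(co, reproductive_values = FALSE)
    p <- lt$params
    expect_lt(abs(p$residual), 1e-10)
    expect_equal(p$lambda, exp(p$r), tolerance = 1e-14)
    expect_equal(p$T, log(p$R0) / p$r, tolerance = 1e-12)
    # offspring conservation along the matrix path
    expect_equal(sum(lt$curves$lxmx), sum(co$fecundity$eggs) / co$n,
                 tolerance = 1e-12)
    expect_gte(p$GRR, p$R0)
    expect_true((p$R0 > 1) == (p$r > 0))
    expect_true((p$R0 > 1) == (p$lambda > 1))
  }
})

test_that("adding eggs to a female weakly increases R0 and r", {
  co1 <- control_fixture()
  fec2 <- co1$fecundity
  fec2$eggs[1] <- fec2$eggs[1] + 50
  co2 <- cohort(co1$records, fec2)
  p1 <- solve_r(compute_mx(compute_sxj(co1), co1))
  p2 <- solve_r(compute_mx(compute_sxj(co2), co2))
  expect_gt(p2$R0, p1$R0)
  expect_gt(p2$r, p1$r)
})

test_that("life expectancy matches direct mean-lifespan oracles", {
  # everyone lives exactly 10 days
  rec <- rbind(adult_rec("a", "female", egg = 2, larva = 3, pupa = 2, longevity = 3),
               adult_rec("b", "male", egg = 2, larva = 3, pupa = 2, longevity = 3))
  e <- life_expectancy(cohort(rec))
  expect_equal(unname(e["0", "egg"]), 10)
  # lifespans 2 and 5 -> e at (0, egg) = 3.5
  co <- cohort(rbind(death_rec("a", "egg", egg = 2),
                     death_rec("b", "larva", egg = 2, larva = 3)))
  e <- life_expectancy(co)
  expect_equal(unname(e["0", "egg"]), 3.5)
  # generated cohorts: e0,egg equals the brute-force mean lifespan
  for (seed in c(4, 9)) {
    co <- simulate_cohort(default_params("30", n = 150), seed = seed)
    e <- life_expectancy(co)
    expect_equal(unname(e["0", "egg"]), mean(lifespan(co)), tolerance = 1e-10)
  }
  # unoccupied cells are NA, occupied terminal cells count their final day
  co <- cohort(death_rec("a", "egg", egg = 2))
  e <- life_expectancy(co)
  expect_true(is.na(e["0", "larva"]))
  expect_equal(unname(e["1", "egg"]), 1)
})

test_that("life expectancy is bounded and trends downward with adult age", {
  # Strict monotonicity does not hold for empirical age-stage life
  # expectancy: terminal cells hold few individuals, so estimated hazards
  # are noisy and e_xj fluctuates near the tail. What the construction
  # does guarantee: every occupied cell counts its current day (e >= 1),
  # remaining life cannot fall by more than a day per day of age
  # (e_x <= 1 + e_{x+1}), and the adult-stage trend is strongly negative.
  for (seed in c(3, 21, 55)) {
    co <- simulate_cohort(default_params("0", n = 1000), seed = seed)
    e <- life_expectancy(co)
    expect_true(all(e[!is.na(e)] >= 1))
    for (stage in c("female", "male")) {
      col <- e[, stage]
      occ <- which(!is.na(col))
      expect_true(all(diff(occ) == 1))  # no gaps in adult occupancy
      expect_true(all(diff(col[occ]) >= -1 - 1e-9))
      expect_lt(cor(col[occ], occ), -0.8)
    }
  }
})

test_that("reproductive value equals discounted future offspring", {
  # undiscounted (r = 0): a lone female laying 5 eggs tomorrow then dying
  # is worth exactly those 5 eggs today
  rec <- adult_rec("f", "female", egg = 1, larva = 1, pupa = 1, longevity = 2)
  co <- cohort(rec, data.frame(id = "f", adult_day = 2, eggs = 5))
  v <- reproductive_value(co, params = list(r = 0))
  expect_equal(unname(v["3", "female"]), 5)  # age 3 = first adult day
  expect_equal(unname(v["4", "female"]), 5)  # laying day itself
  # male reproductive values are identically zero
  co <- control_fixture()
  lt <- lifetable(co)
  vm <- lt$vxj[, "male"]
  expect_true(all(vm[!is.na(vm)] == 0))
  # peak near reproduction onset: v at first adult-female age >= v at the
  # last reproductive age
  rec <- co$records
  fec <- co$fecundity
  m <- match(fec$id, rec$id)
  ages_lay <- rec$egg_d[m] + rec$larva_d[m] + rec$pupa_d[m] + fec$adult_day - 1
  vf <- lt$vxj[, "female"]
  occ <- which(!is.na(vf))
  expect_gte(vf[occ[1]], vf[as.character(max(ages_lay))])
  # enumeration oracle on a cohort with homogeneous stage timing: v must
  # equal the mean discounted future eggs of the cell's occupants
  r <- lt$params$r
  for (x in c(16, 20, 24)) {  # adult-female ages in this fixture
    fem_ids <- rec$id[rec$sex == "female" &
                        rec$egg_d + rec$larva_d + rec$pupa_d +
                        rec$adult_longevity_d > x]
    future <- vapply(fem_ids, function(id) {
      sel <- fec$id == id & ages_lay >= x
      sum(fec$eggs[sel] * exp(-r * (ages_lay[sel] + 1)))
    }, numeric(1))
    expect_equal(unname(lt$vxj[as.character(x), "female"]),
                 exp(r * (x + 1)) * mean(future), tolerance = 1e-9)
  }
})

test_that("reproduction summaries count females, periods and survivorship", {
  co <- control_fixture()
  s <- summarize_reproduction(co)
  expect_equal(s$Fn, 9)
  expect_equal(s$male_count, 10)
  expect_equal(s$Sa, 0.95)
  expect_equal(s$female_fraction, 0.45)
  expect_equal(s$F, 1874 / 9)
  expect_equal(s$RepF, 9)
  # single female: emergence age 16, first egg at age 18
  co <- cohort(adult_rec("f", "female", egg = 3, larva = 7, pupa = 6,
                         longevity = 14),
               data.frame(id = "f", adult_day = 3, eggs = 4))
  s <- summarize_reproduction(co)
  expect_equal(s$APOP, 2)
  expect_equal(s$TPOP, 18)
  expect_equal(s$ovi_days, 1)
  # no reproduction: periods undefined and flagged
  co <- cohort(adult_rec("f", "female"))
  s <- summarize_reproduction(co)
  expect_true(is.na(s$APOP))
  expect_match(s$flags, "no reproductive females")
})

test_that("life-table output tables round-trip through TSV/JSON", {
  lt <- lifetable(control_fixture())
  dir <- tempfile()
  files <- write_lifetable(lt, dir, prefix = "ctl")
  expect_true(all(file.exists(files)))
  curves <- read.delim(files[1])
  expect_equal(curves$lxmx, lt$curves$lxmx)
  pj <- jsonlite::read_json(files[3])
  expect_equal(pj$r, lt$params$r)
  expect_equal(pj$Sa, 0.95)
  expect_match(pj$meta$exj_vxj_convention, "hypothetical")
})
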