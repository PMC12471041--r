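# Builders for hand-made cohorts and independent brute-force oracles.

adult_rec <- function(id, sex, egg = 3, larva = 7, pupa = 6, longevity = 14,
                      treatment = "0") {
  data.frame(id = id, treatment = treatment, egg_d = egg, larva_d = larva,
             pupa_d = pupa, sex = sex, death_stage = "adult",
             adult_longevity_d = longevity, stringsAsFactors = FALSE)
}

death_rec <- function(id, stage, egg = 3, larva = NA, pupa = NA,
                      treatment = "0") {
  data.frame(id = id, treatment = treatment, egg_d = egg, larva_d = larva,
             pupa_d = pupa, sex = "undetermined", death_stage = stage,
             adult_longevity_d = 0, stringsAsFactors = FALSE)
}

# constant laying schedule: `total` eggs split over `days` laying days
# starting on adult day `first`
fec_rows <- function(id, total, days = 4, first = 3) {
  per <- total %/% days
  eggs <- rep(per, days)
  eggs[1] <- eggs[1] + total - per * days
  data.frame(id = id, adult_day = first + seq_len(days) - 1, eggs = eggs,
             stringsAsFactors = FALSE)
}

# Deterministic 20-individual cohort reproducing the control-group
# bookkeeping of the study design: 9 females (1874 eggs in total, so mean
# eggs per female 208.22), 10 males, 1 larval death => Sa = 0.95.
control_fixture <- function() {
  females <- do.call(rbind, lapply(1:9, function(i)
    adult_rec(sprintf("f%02d", i), "female", longevity = 14)))
  males <- do.call(rbind, lapply(1:10, function(i)
    adult_rec(sprintf("m%02d", i), "male", longevity = 12)))
  dead <- death_rec("d01", "larva", egg = 3, larva = 4)
  totals <- c(rep(208, 8), 210)  # 1874 eggs
  fec <- do.call(rbind, Map(fec_rows, sprintf("f%02d", 1:9), totals))
  cohort(rbind(females, males, dead), fec)
}

# 30 mg L-1-like fixture: 4 females (287 eggs total => F = 71.75), 6 males,
# 10 preadult deaths => Sa = 0.50, female fraction 0.20.
mid_dose_fixture <- function() {
  females <- do.call(rbind, lapply(1:4, function(i)
    adult_rec(sprintf("f%02d", i), "female", egg = 4, larva = 11, pupa = 7,
              longevity = 13, treatment = "30")))
  males <- do.call(rbind, lapply(1:6, function(i)
    adult_rec(sprintf("m%02d", i), "male", egg = 4, larva = 11, pupa = 7,
              longevity = 12, treatment = "30")))
  dead <- do.call(rbind, lapply(1:10, function(i)
    death_rec(sprintf("d%02d", i), "larva", egg = 4, larva = 5,
              treatment = "30")))
  totals <- c(72, 72, 72, 71)  # 287 eggs
  fec <- do.call(rbind, Map(fec_rows, sprintf("f%02d", 1:4), totals))
  cohort(rbind(females, males, dead), fec)
}

# 300 mg L-1-like fixture: 3 females (142 eggs => F = 47.33), 5 males,
# 12 preadult deaths => Sa = 0.40, female fraction 0.15.
high_dose_fixture <- function() {
  females <- do.call(rbind, lapply(1:3, function(i)
    adult_rec(sprintf("f%02d", i), "female", egg = 4, larva = 12, pupa = 7,
              longevity = 10, treatment = "300")))
  males <- do.call(rbind, lapply(1:5, function(i)
    adult_rec(sprintf("m%02d", i), "male", egg = 4, larva = 12, pupa = 7,
              longevity = 9, treatment = "300")))
  dead <- do.call(rbind, lapply(1:12, function(i)
    death_rec(sprintf("d%02d", i), "larva", egg = 4, larva = 6,
              treatment = "300")))
  totals <- c(47, 47, 48)  # 142 eggs
  fec <- do.call(rbind, Map(fec_rows, sprintf("f%02d", 1:3), totals))
  cohort(rbind(females, males, dead), fec)
}

# Independent brute-force roll call: for each individual walk its record
# day by day and tally who is alive in which stage, without using the
# package's occupancy code path.
brute_force_sxj <- function(co) {
  rec <- co$records
  n <- nrow(rec)
  days_alive <- function(i) {
    d <- c(rec$egg_d[i], rec$larva_d[i], rec$pupa_d[i], rec$adult_longevity_d[i])
    sum(d, na.rm = TRUE)
  }
  xmax <- max(vapply(seq_len(n), days_alive, numeric(1))) - 1
  out <- matrix(0, xmax + 1, 5, dimnames = list(0:xmax, STAGES))
  for (i in seq_len(n)) {
    age <- 0
    for (stage in c("egg", "larva", "pupa")) {
      d <- rec[[paste0(stage, "_d")]][i]
      if (is.na(d)) break
      for (k in seq_len(d)) {
        out[age + 1, stage] <- out[age + 1, stage] + 1
        age <- age + 1
      }
    }
    if (rec$death_stage[i] == "adult") {
      stage <- if (rec$sex[i] == "female") "female" else "male"
      for (k in seq_len(rec$adult_longevity_d[i])) {
        out[age + 1, stage] <- out[age + 1, stage] + 1
        age <- age + 1
      }
    }
  }
  out / n
}
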