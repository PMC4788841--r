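# Fixtures built in code: a minimal observation-row constructor and the
# handcrafted cascade table in which each cleaning filter removes exactly
# one known patient.

obs_row <- function(id, date, height = NA_real_, weight = NA_real_,
                    sex = "female", birth = as.Date("1970-06-15"),
                    postal = "K7M1A1", edb = as.Date(NA)) {
  tibble::tibble(patient_id = id, sex = sex, birth_date = as.Date(birth),
                 postal_code = postal, height = height, weight = weight,
                 observation_date = as.Date(date), pregnancy_edb = edb)
}

# Nine patients: A under-age, B duplicated row, C pregnancy window,
# D missing height, E implausible BMI, F inconsistent repeat measures,
# G/H/I clean (G-I give the variation screen its comparison cohort).
cascade_fixture <- function() {
  dplyr::bind_rows(
    obs_row("A", "2011-03-01", 1.70, 70, birth = as.Date("1992-05-01")),
    obs_row("B", "2011-02-01", 1.70, 70),
    obs_row("B", "2011-02-01", 1.70, 70),                      # exact dup
    obs_row("C", "2011-03-01", 1.65, 60, edb = as.Date("2011-06-01")),
    obs_row("D", "2011-04-01", NA, 80),
    obs_row("E", "2011-05-01", 1.60, 140.8),                   # BMI 55
    obs_row("F", "2011-03-01", 1.60, 51.2),                    # BMI 20
    obs_row("F", "2011-09-01", 1.60, 89.6),                    # BMI 35
    obs_row("G", "2011-01-10", 1.60, 64.0),
    obs_row("G", "2011-06-10", 1.60, 64.5),
    obs_row("H", "2011-01-11", 1.60, 64.0),
    obs_row("H", "2011-06-11", 1.60, 64.3),
    obs_row("I", "2011-01-12", 1.60, 64.0),
    obs_row("I", "2011-06-12", 1.60, 64.8))
}

# quasi-identifier table builder for the de-identification tests
qi_table <- function(postal, birth, sex = "female",
                     id = sprintf("P%03d", seq_along(postal))) {
  tibble::tibble(patient_id = id, postal_code = postal,
                 birth_date = as.Date(birth), sex = sex)
}

# random quasi-identifier table for property-style tests
random_qi_table <- function(n) {
  pool_postal <- c("K7M1A1", "K7M1A2", "K7M2B1", "K7L3C4", "K7L3C5",
                   "K0H1X0", "K0H2Y0", "M5V1B1")
  pool_birth <- as.Date(c("1950-02-01", "1961-07-12", "1978-11-30",
                          "1990-04-04"))
  qi_table(sample(pool_postal, n, replace = TRUE),
           sample(pool_birth, n, replace = TRUE),
           sex = sample(c("female", "male"), n, replace = TRUE))
}

# independent brute-force Pearson statistic (plain double loop)
brute_force_pearson <- function(m) {
  total <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / total
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  stat
}

random_contingency <- function(nr, nc) {
  matrix(stats::rpois(nr * nc, 8) + 1L, nrow = nr, ncol = nc)
}
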