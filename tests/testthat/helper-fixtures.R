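# Shared fixture builders. Everything is generated in code; tests never
# read stored data files.

DAY0 <- as.Date("2010-01-01")

# fills at day offsets `days` (relative to DAY0) with matching supplies
make_fills <- function(days, supplies, patient = "P1",
                       ingredient = "metformin",
                       indication = "diabetes_oral") {
  tibble::tibble(
    patient_id = patient,
    fill_date = DAY0 + days,
    ingredient = ingredient,
    indication = indication,
    days_supply = as.integer(supplies))
}

make_eligibility <- function(ids, continuous = TRUE, dual = FALSE) {
  tibble::tibble(patient_id = ids,
                 continuous_benefits = rep_len(continuous, length(ids)),
                 dual_coverage = rep_len(dual, length(ids)))
}

make_response <- function(patient = "P1", source = "atsm",
                          indication = "diabetes_oral", day = 400,
                          missed = 0) {
  tibble::tibble(patient_id = patient, source = source,
                 indication = indication, response_date = DAY0 + day,
                 missed_days = as.integer(missed))
}

write_temp_csv <- function(df, lines = NULL) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  if (is.null(lines)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    writeLines(lines, path)
  }
  path
}

# random fill sequence for property suites: n fills, supplies 1-120 d,
# spacings 1-200 d
random_fill_sequence <- function(n_fills = sample(2:8, 1)) {
  spacings <- sample(1:200, n_fills - 1, replace = TRUE)
  make_fills(days = cumsum(c(0L, spacings)),
             supplies = sample(1:120, n_fills, replace = TRUE))
}

# independent brute-force Freeman-Halton oracle: enumerate the full grid
# of free cells, reconstruct the rest from the margins, keep feasible
# tables, and total the exact factorial probabilities of tables no more
# probable than the observed one
brute_force_fisher <- function(m) {
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) return(1)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  r <- nrow(m); c <- ncol(m)
  prob <- function(tab) {
    prod(factorial(rs)) * prod(factorial(cs)) /
      (factorial(n) * prod(factorial(tab)))
  }
  free <- expand.grid(lapply(seq_len((r - 1) * (c - 1)),
                             function(i) 0:n))
  p_obs <- prob(m)
  total <- 0
  for (k in seq_len(nrow(free))) {
    tab <- matrix(0, r, c)
    tab[seq_len(r - 1), seq_len(c - 1)] <- as.numeric(free[k, ])
    tab[seq_len(r - 1), c] <- rs[seq_len(r - 1)] -
      rowSums(tab[seq_len(r - 1), seq_len(c - 1), drop = FALSE])
    tab[r, ] <- cs - colSums(tab[seq_len(r - 1), , drop = FALSE])
    if (any(tab < 0)) next
    p <- prob(tab)
    if (p <= p_obs * (1 + 1e-12)) total <- total + p
  }
  min(1, total)
}

# random margins for an r x 2 table with total n <= n_max, realized as an
# actual random table so margins are always feasible
random_table <- function(r, n_max = 25) {
  n <- sample(4:n_max, 1)
  cells <- tabulate(sample.int(r * 2, n, replace = TRUE), nbins = r * 2)
  matrix(cells, nrow = r, ncol = 2)
}
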