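# Brute-force pair-enumeration oracles, written as plain double loops so
# they stay independent of the package's compiled kernels.

# Harrell C: usable pairs are those whose earlier time is an event; ties
# on time between two events are usable with 0.5 credit; an event tied in
# time with a censoring is treated as the earlier observation.
brute_harrell_c <- function(score, time, event) {
  n <- length(score)
  usable <- 0
  credit <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] == 1 && event[j] == 1) {
          usable <- usable + 1
          credit <- credit + 0.5
        } else if (event[i] != event[j]) {
          se <- if (event[i] == 1) score[i] else score[j]
          sc <- if (event[i] == 1) score[j] else score[i]
          usable <- usable + 1
          credit <- credit + if (se > sc) 1 else if (se == sc) 0.5 else 0
        }
      } else {
        first <- if (time[i] < time[j]) i else j
        second <- if (time[i] < time[j]) j else i
        if (event[first] == 1) {
          usable <- usable + 1
          credit <- credit +
            if (score[first] > score[second]) 1
            else if (score[first] == score[second]) 0.5 else 0
        }
      }
    }
  }
  credit / usable
}

# Goenen-Heller concordance probability: mean of 1/(1+exp(-|d|)) over
# pairs with distinct values; tied pairs excluded.
brute_cpe <- function(eta) {
  n <- length(eta)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- abs(eta[i] - eta[j])
      if (d > 0) {
        np <- np + 1
        tot <- tot + 1 / (1 + exp(-d))
      }
    }
  }
  if (np == 0) 0.5 else tot / np
}

# Small proportional-hazards simulator with exponential baseline, used by
# the model-fitting tests (kept separate from the package's generator).
sim_ph_data <- function(n, beta, base_rate = 0.05, censor = c(5, 25),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("x", seq_len(p))
  lp <- as.matrix(x) %*% beta
  t_ev <- rexp(n, base_rate * exp(lp))
  t_c <- runif(n, censor[1], censor[2])
  list(
    covariates = x,
    outcomes = data.frame(time = pmin(t_ev, t_c),
                          event = as.integer(t_ev <= t_c)),
    lp = drop(lp)
  )
}

# A tiny hand-buildable cohort used across reader/endpoint tests.
toy_cohort <- function() {
  data.frame(
    id = c("a", "b", "c"),
    age_years = c(4, 10, 7.5),
    wbc = c(10, 52.1, 3.4),
    d8_mrd = c(0, 0.02, 1e-3),
    d29_mrd = c(1e-4, 5e-3, NA),
    frg = c(TRUE, FALSE, FALSE),
    urg = c(FALSE, TRUE, FALSE),
    cns = c("CNS1", "CNS3", "CNS2"),
    nci_risk = c("SR", "HR", "SR"),
    event_type = c("none", "relapse", "smn"),
    time_from_eoi_years = c(6.0, 2.5, 3.0),
    stringsAsFactors = FALSE
  )
}
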