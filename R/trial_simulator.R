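#' Fat-free mass from body weight
#'
#' Sex-specific power functions relating fat-free mass to body weight,
#' derived empirically from the study population:
#' `FFM = 2.541 * WT^0.728` (male) and `FFM = 2.496 * WT^0.669` (female).
#'
#' @param wt body weight, kg (vectorised).
#' @param sex `"male"` or `"female"` (recycled).
#' @return fat-free mass, kg.
#' @export
#' @examples
#' ffm_from_wt(53.9, "male")
ffm_from_wt <- function(wt, sex) {
  stopifnot(all(wt > 0), all(sex %in% c("male", "female")))
  ifelse(sex == "male", 2.541 * wt^0.728, 2.496 * wt^0.669)
}

## Truncated-normal draws by inverse-CDF: exact, vectorised, seed-friendly.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Sample virtual-cohort covariates
#'
#' Draws a virtual tuberculosis cohort with the study population's covariate
#' structure: sex is Bernoulli with 71.1\% male; body weight is drawn per sex
#' from a normal distribution truncated to the observed range (male: mean
#' 55.8, SD 7.4, range 40.7-74.0 kg; female: mean 53.8, SD 10.7, range
#' 40.2-84.2 kg); fat-free mass follows deterministically from
#' [ffm_from_wt()]. The truncated normal stands in for the unpublished
#' empirical weight distribution, of which only these moments are reported.
#'
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @param pct_male probability of male sex.
#' @param wt_male,wt_female `c(mean, sd, lower, upper)` of the per-sex
#'   truncated-normal weight distributions, kg.
#' @return tibble with columns `id`, `sex`, `wt`, `ffm`.
#' @export
#' @examples
#' sample_covariates(5, seed = 1)
sample_covariates <- function(n, seed = NULL, pct_male = 0.711,
                              wt_male = c(55.8, 7.4, 40.7, 74.0),
                              wt_female = c(53.8, 10.7, 40.2, 84.2)) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  sex <- ifelse(runif(n) < pct_male, "male", "female")
  wt <- numeric(n)
  m <- sex == "male"
  wt[m] <- rtruncnorm(sum(m), wt_male[1], wt_male[2], wt_male[3], wt_male[4])
  wt[!m] <- rtruncnorm(sum(!m), wt_female[1], wt_female[2], wt_female[3],
                       wt_female[4])
  tibble::tibble(id = seq_len(n), sex = sex, wt = wt,
                 ffm = ffm_from_wt(wt, sex))
}

#' Draw individual and per-occasion random effects
#'
#' IIV etas are multivariate normal on the log scale with the parameter
#' set's standard deviations and the single Vmax-km correlation; IOV etas
#' are independent normal per subject, occasion and parameter. For the
#' `no_iov` variant all occasion etas are exactly zero.
#'
#' @param params a [rif_params()] object.
#' @param n_subjects number of subjects.
#' @param occasion_days integer visit days carrying occasion etas.
#' @param seed optional integer seed.
#' @return list with `iiv` (n x 6 matrix, columns vmax, km, v, ka, mtt, nn)
#'   and `iov` (n x days x 4 array, dimnames `day` x `param`).
#' @export
draw_etas <- function(params, n_subjects, occasion_days = c(1, 7, 14),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Om <- iiv_cov(params)
  ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) {
    stop("IIV covariance is not positive semi-definite", call. = FALSE)
  }
  iiv <- MASS::mvrnorm(n_subjects, mu = rep(0, 6), Sigma = Om)
  if (n_subjects == 1) iiv <- matrix(iiv, nrow = 1)
  colnames(iiv) <- IIV_NAMES
  nd <- length(occasion_days)
  iov <- array(0, dim = c(n_subjects, nd, 4),
               dimnames = list(NULL, as.character(occasion_days), IOV_NAMES))
  for (k in seq_along(IOV_NAMES)) {
    sdk <- params$iov_sd[[IOV_NAMES[k]]]
    if (sdk > 0) iov[, , k] <- rnorm(n_subjects * nd, 0, sdk)
  }
  list(iiv = iiv, iov = iov)
}

## One subject's occasion-eta matrix (rows = days) from a draw_etas() array.
iov_slice <- function(iov_array, i) {
  m <- iov_array[i, , , drop = FALSE]
  dim(m) <- dim(iov_array)[2:3]
  dimnames(m) <- dimnames(iov_array)[2:3]
  m
}

#' Sparse PK sampling schedule
#'
#' @param days visit days (occasions), default days 1, 7 and 14.
#' @param offsets within-day sampling times in hours relative to that day's
#'   dose; default 5 min pre-dose and 2 and 4 h post-dose.
#' @return list with fields `days` and `offsets`.
#' @export
sampling_schedule <- function(days = c(1, 7, 14), offsets = c(-5 / 60, 2, 4)) {
  stopifnot(!is.unsorted(days), !is.unsorted(offsets), offsets[1] < 0 || all(offsets >= 0))
  list(days = as.integer(days), offsets = offsets)
}

#' Simulate observed concentrations for one subject
#'
#' Simulates the noise-free profile at the scheduled sampling times, applies
#' log-additive residual error (`observed = exp(log(pred) + e)`,
#' `e ~ N(0, sigma_log^2)`) and censors observations below the lower limit
#' of quantification: censored records are flagged `BLQ = 1` and carry the
#' LLOQ value in `DV` rather than a concentration. Predictions of exactly
#' zero (e.g. the pre-dose sample on day 1) are recorded as BLQ. The result
#' is a long-format dataset of dose and observation events.
#'
#' @inheritParams simulate_profile
#' @param schedule a [sampling_schedule()]; only days covered by `regimen`
#'   are sampled.
#' @param sigma_log residual SD on the log scale; 0 gives noise-free
#'   observations.
#' @param lloq lower limit of quantification, mg/L.
#' @param seed optional integer seed.
#' @param id subject identifier stored in the dataset.
#' @return tibble with NONMEM-style columns `ID`, `TIME`, `AMT`, `DV`,
#'   `EVID`, `MDV`, `BLQ`, `OCC`, `SEX`, `WT`, `FFM`. `OCC` is the occasion
#'   index of an observation (`NA` on dose rows); BLQ rows carry the LLOQ in
#'   `DV`.
#' @export
simulate_observations <- function(params, subject, regimen,
                                  schedule = sampling_schedule(),
                                  eta_iiv = zero_iiv(), iov_etas = NULL,
                                  sigma_log = params$sigma_log, lloq = 0.3,
                                  seed = NULL, id = NULL,
                                  rtol = 1e-8, atol = 1e-10) {
  if (lloq <= 0) stop("lloq must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- as_subject(subject)
  if (is.null(id)) id <- if (!is.null(s$id)) s$id else 1L
  days <- schedule$days[24 * (schedule$days - 1) <= max(regimen$time)]
  obs_time <- as.vector(vapply(days, function(d) 24 * (d - 1) + schedule$offsets,
                               numeric(length(schedule$offsets))))
  occ <- rep(match(days, schedule$days), each = length(schedule$offsets))
  prof <- simulate_profile(params, s, regimen, obs_time, eta_iiv, iov_etas,
                           rtol, atol)
  pred <- prof$conc
  eps <- if (sigma_log > 0) rnorm(length(pred), 0, sigma_log) else 0
  dv <- ifelse(pred > 0, exp(log(pmax(pred, 1e-300)) + eps), 0)
  blq <- as.integer(dv < lloq | pred <= 0)
  dv[blq == 1] <- lloq
  sx <- if (!is.null(s$sex)) s$sex else NA_character_
  dose_rows <- tibble::tibble(
    ID = id, TIME = regimen$time, AMT = regimen$amt, DV = NA_real_,
    EVID = 1L, MDV = 1L, BLQ = NA_integer_, OCC = NA_integer_,
    SEX = sx, WT = s$wt, FFM = s$ffm
  )
  obs_rows <- tibble::tibble(
    ID = id, TIME = obs_time, AMT = NA_real_, DV = dv,
    EVID = 0L, MDV = 0L, BLQ = blq, OCC = occ,
    SEX = sx, WT = s$wt, FFM = s$ffm
  )
  ds <- dplyr::bind_rows(dose_rows, obs_rows)
  ## doses precede same-time observations; the pre-dose sample (just before
  ## its dose) sorts naturally by time
  ds[order(ds$TIME, ds$EVID == 0L), ]
}

#' Weight-based starting dose on the 300-mg tablet grid
#'
#' `wt * mg_per_kg` rounded to the nearest multiple of the tablet increment
#' (ties rounded down, for safety), with a floor at the minimum dose.
#'
#' @param wt body weight, kg (vectorised).
#' @param mg_per_kg weight-normalised dose level, mg/kg.
#' @param increment tablet strength increment, mg.
#' @param min_dose minimum dose, mg.
#' @return dose in mg on the increment grid.
#' @export
#' @examples
#' assign_initial_dose(53.9, 35) # 1886.5 -> 1800
assign_initial_dose <- function(wt, mg_per_kg = 35, increment = 300,
                                min_dose = 600) {
  stopifnot(all(wt > 0), mg_per_kg >= 0)
  raw <- wt * mg_per_kg
  d <- increment * ceiling(raw / increment - 0.5)
  pmax(d, min_dose)
}

#' Read and write NONMEM-style datasets
#'
#' Long-format CSV with a mandatory header row and missing values written as
#' `"."`. `read_nm_dataset(write_nm_dataset(ds, f))` reproduces the dataset.
#'
#' @param ds dataset tibble as produced by [simulate_observations()].
#' @param path file path.
#' @return `write_nm_dataset()` returns `path` invisibly;
#'   `read_nm_dataset()` returns the dataset tibble.
#' @export
write_nm_dataset <- function(ds, path) {
  out <- as.data.frame(ds)
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), ".",
                          sprintf("%.12g", out[[nm]]))
    } else {
      out[[nm]] <- ifelse(is.na(out[[nm]]), ".", as.character(out[[nm]]))
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nm_dataset
#' @export
read_nm_dataset <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  num <- c("TIME", "AMT", "DV", "WT", "FFM")
  int <- c("ID", "EVID", "MDV", "BLQ", "OCC")
  for (nm in intersect(num, names(raw))) {
    raw[[nm]] <- as.numeric(ifelse(raw[[nm]] == ".", NA, raw[[nm]]))
  }
  for (nm in intersect(int, names(raw))) {
    raw[[nm]] <- as.integer(ifelse(raw[[nm]] == ".", NA, raw[[nm]]))
  }
  tibble::as_tibble(raw)
}
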