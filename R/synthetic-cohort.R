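# Synthetic resting-state cohort generator: block-correlated regional
# signals with AR(1) temporal structure, sex-by-disease coupling effects,
# recorded nuisance contamination, and Table-style demographics.

# truncated-normal draws by rejection (moments match the target closely
# for the mild truncations used here)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

# demographic / clinical moments the generator emulates, per 2x2 cell
.cellMoments <- list(
  control.female = list(age = c(31.1, 9.3)),
  control.male   = list(age = c(33.3, 2.1)),
  patient.female = list(age = c(32.3, 8.7), duration = c(10.9, 7.4),
                        attackDuration = c(12.9, 7.7), frequency = c(4.0, 1.9),
                        intensity = c(5.4, 1.7)),
  patient.male   = list(age = c(33.0, 7.9), duration = c(8.1, 2.3),
                        attackDuration = c(14.5, 4.4), frequency = c(4.4, 2.1),
                        intensity = c(5.2, 1.2)))

.moduleAssignment <- function(nRegions, nModules) {
  sort(rep_len(seq_len(nModules), nRegions))
}

# subject-level region correlation matrix: block structure plus the
# subject's coupling perturbation on the affected within-module pairs
.subjectCorrelation <- function(config, affected, couplingDelta) {
  n <- config@nRegions
  mod <- .moduleAssignment(n, config@nModules)
  same <- outer(mod, mod, "==")
  r <- matrix(config@betweenModuleR, n, n)
  r[same] <- config@withinModuleR
  if (length(affected) && couplingDelta != 0) {
    aff <- rep(FALSE, n)
    aff[affected] <- TRUE
    hit <- outer(aff, aff, "&") & same
    r[hit] <- pmin(0.95, pmax(-0.95, r[hit] + couplingDelta))
  }
  diag(r) <- 1
  r
}

# draw an n_regions x n_timepoints signal with the given correlation and
# AR(1) temporal autocorrelation (variance-normalized innovations keep the
# lag-0 cross-correlation equal to the target)
.drawSignal <- function(r, nTimepoints, phi) {
  x <- MASS::mvrnorm(nTimepoints, mu = rep(0, nrow(r)), Sigma = r)
  x <- t(x)
  if (phi != 0) {
    innov <- x * sqrt(1 - phi^2)
    x <- t(apply(innov, 1, function(row)
      as.numeric(stats::filter(row, phi, method = "recursive"))))
  }
  x
}

.drawNuisance <- function(nTimepoints, phi = 0.95) {
  smooth <- function(scale) {
    w <- as.numeric(stats::filter(stats::rnorm(nTimepoints), phi,
                                  method = "recursive"))
    w <- w - mean(w)
    peak <- max(abs(w))
    if (peak == 0) peak <- 1
    w / peak * scale
  }
  # slow drifts well inside the 1.5 mm / 1.5 degree screening limits
  motion <- rbind(smooth(stats::runif(1, 0.1, 0.6)),
                  smooth(stats::runif(1, 0.1, 0.6)),
                  smooth(stats::runif(1, 0.1, 0.6)),
                  smooth(stats::runif(1, 0.1, 0.5)),
                  smooth(stats::runif(1, 0.1, 0.5)),
                  smooth(stats::runif(1, 0.1, 0.5)))
  ar1 <- function() {
    w <- as.numeric(stats::filter(stats::rnorm(nTimepoints) * sqrt(1 - 0.3^2),
                                  0.3, method = "recursive"))
    w
  }
  NuisanceSet(motion, ar1(), ar1())
}

.makeSubjectRows <- function(config) {
  cells <- expand.grid(sex = c("female", "male"),
                       group = c("control", "patient"),
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sex <- cells$sex[i]; group <- cells$group[i]
    nSub <- if (sex == "female") config@nFemalePerGroup else
      config@nMalePerGroup
    mom <- .cellMoments[[paste(group, sex, sep = ".")]]
    age <- .rtruncnorm(nSub, mom$age[1], mom$age[2], 18, 65)
    df <- data.frame(sex = rep(sex, nSub), group = rep(group, nSub),
                     age = age, disease_duration = NA_real_,
                     attack_frequency = NA_real_, attack_duration = NA_real_,
                     pain_intensity = NA_real_, stringsAsFactors = FALSE)
    if (group == "patient") {
      # duration partially driven by age so age is a genuine confound
      ageZ <- (age - mom$age[1]) / mom$age[2]
      dRaw <- mom$duration[1] + mom$duration[2] *
        (0.6 * ageZ + sqrt(1 - 0.6^2) * stats::rnorm(nSub))
      df$disease_duration <- pmin(pmax(dRaw, 0.5), 45)
      df$attack_frequency <- .rtruncnorm(nSub, mom$frequency[1],
                                         mom$frequency[2], 0.5, 15)
      df$attack_duration <- .rtruncnorm(nSub, mom$attackDuration[1],
                                        mom$attackDuration[2], 1, 72)
      df$pain_intensity <- .rtruncnorm(nSub, mom$intensity[1],
                                       mom$intensity[2], 0, 10)
    }
    df
  }))
  rows$subject_id <- sprintf("sub%03d", seq_len(nrow(rows)))
  rows[, c("subject_id", "sex", "group", "age", "disease_duration",
           "attack_frequency", "attack_duration", "pain_intensity")]
}

#' Generate a synthetic resting-state cohort
#'
#' Realizes the full 2x2 sex-by-disease study: per-subject demographics
#' drawn from truncated normals matching the emulated cell moments,
#' regional time series drawn from a modular (block) correlation structure
#' with AR(1) temporal autocorrelation, and nuisance components (six
#' rigid-body motion traces, white-matter and ventricle signals) linearly
#' mixed into the regional signals with recorded weights.
#'
#' Patients receive an additive reduction of within-module coupling on the
#' affected regions (\code{diseaseEffect}); female patients an extra
#' reduction (\code{sexDiseaseInteraction}); and each patient's coupling is
#' additionally shifted by \code{durationSlope} per year of migraine
#' duration (centered), which makes duration recoverable downstream by an
#' age-controlled partial correlation.
#'
#' @param config a \linkS4class{CohortConfig}; its seed makes the cohort
#'   bit-identical across calls.
#' @param regionLabels node labels; default \code{\link{aalRegionLabels}}
#'   when \code{nRegions} is 90, otherwise generic labels.
#' @return A \linkS4class{SyntheticCohort}.
#' @examples
#' cfg <- cohortConfig(nFemalePerGroup = 2, nMalePerGroup = 2,
#'                     nRegions = 20, nTimepoints = 60, seed = 7)
#' coh <- generateCohort(cfg)
#' table(subjectTable(coh)$group, subjectTable(coh)$sex)
#' @export
generateCohort <- function(config, regionLabels = NULL) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  if (is.null(regionLabels)) {
    regionLabels <- if (config@nRegions == 90) aalRegionLabels() else
      sprintf("R%03d", seq_len(config@nRegions))
  }
  stopifnot(length(regionLabels) == config@nRegions)
  affected <- config@affectedRegions
  if (!length(affected)) affected <- seq_len(config@nRegions)
  withr::with_seed(as.integer(config@seed), {
    subjects <- .makeSubjectRows(config)
    refDuration <- 11.3  # cohort-level mean migraine duration (years)
    series <- vector("list", nrow(subjects))
    nuisance <- vector("list", nrow(subjects))
    mixing <- vector("list", nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      isPatient <- subjects$group[i] == "patient"
      isFemale <- subjects$sex[i] == "female"
      delta <- 0
      if (isPatient) {
        delta <- -config@diseaseEffect -
          (if (isFemale) config@sexDiseaseInteraction else 0) +
          config@durationSlope * (subjects$disease_duration[i] - refDuration)
      }
      r <- .subjectCorrelation(config, affected, delta)
      sig <- .drawSignal(r, config@nTimepoints, config@noiseAr1)
      nuis <- .drawNuisance(config@nTimepoints)
      nmat <- rbind(nuis@motion, nuis@wmSignal, nuis@csfSignal)
      nstd <- nmat / pmax(apply(nmat, 1, stats::sd), 1e-12)
      w <- matrix(stats::runif(config@nRegions * 8, -1, 1),
                  config@nRegions, 8) * config@nuisanceWeight
      sig <- sig + w %*% nstd
      series[[i]] <- RoiTimeSeries(sig, regionLabels, config@trSeconds)
      nuisance[[i]] <- nuis
      mixing[[i]] <- w
    }
    names(series) <- subjects$subject_id
    names(nuisance) <- subjects$subject_id
    names(mixing) <- subjects$subject_id
    new("SyntheticCohort", subjects = subjects, series = series,
        nuisance = nuisance, mixing = mixing, config = config)
  })
}
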