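# Synthetic bird-vocalization generator: labeled recordings with known
# ground truth that exercise the whole pipeline in place of field data.

#' Deterministic synthetic species definitions
#'
#' Creates \code{nSpecies} species whose syllables are chirp complexes
#' with primary centre frequencies evenly spaced over the 1.5-10 kHz band,
#' guaranteeing a pairwise separation of at least \code{minSeparation} Hz
#' in the primary component, plus a secondary component and seeded
#' per-species temporal parameters.
#'
#' @param nSpecies number of species (>= 2).
#' @param separation pairwise separation (Hz) of the primary centre
#'   frequencies; \code{NULL} (default) spreads the species evenly over
#'   the band (maximal separation). Small values make species
#'   intentionally confusable.
#' @param seed integer seed.
#' @return list of \linkS4class{SpeciesSpec} objects.
#' @export
makeSpeciesSpecs <- function(nSpecies, separation = NULL, seed = 1) {
  if (nSpecies < 2) stop("nSpecies must be >= 2")
  lo <- 1500; hi <- 10000
  spacing <- if (is.null(separation)) (hi - lo) / (nSpecies - 1) else
    separation
  if (is.null(separation) && spacing < 500) {
    stop(sprintf(
      "cannot separate %d species by 500 Hz inside the %g-%g Hz band",
      nSpecies, lo, hi))
  }
  span <- (nSpecies - 1) * spacing
  if (span > hi - lo) {
    stop(sprintf(
      "cannot separate %d species by %g Hz inside the %g-%g Hz band",
      nSpecies, spacing, lo, hi))
  }
  primary <- (lo + hi) / 2 + (seq_len(nSpecies) - (nSpecies + 1) / 2) * spacing
  withr::with_seed(.childSeed(seed, "specs"), {
    lapply(seq_len(nSpecies), function(i) {
      secondary <- min(max(primary[i] + spacing / 2 +
                             stats::runif(1, -0.1, 0.1) * spacing, 1100),
                       10400)
      methods::new("SpeciesSpec",
        name = sprintf("species%02d", i),
        basisFreqs = c(primary[i], secondary),
        basisWidths = stats::runif(2, 100, 300),
        syllableDurationRange = c(0.08, 0.18),
        syllableRate = stats::runif(1, 2, 3),
        chirpSlopeRange = sort(stats::runif(2, -2000, 2000)))
    })
  })
}

# Tukey-style amplitude envelope: raised-cosine ramps of `ramp` samples at
# both ends, flat in between.
.tukeyEnvelope <- function(n, ramp) {
  ramp <- min(ramp, n %/% 2)
  env <- rep(1, n)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[seq_len(ramp)] <- up
    env[n + 1 - seq_len(ramp)] <- up
  }
  env
}

#' Synthesize one labeled recording
#'
#' Places amplitude-enveloped linear chirps at the species' basis
#' frequencies at randomized intervals governed by the species' syllable
#' rate, and adds white noise at the requested SNR (measured against the
#' band-limited chirp signal power). \code{noiseDb = Inf} yields a clean
#' recording.
#'
#' @param spec a \linkS4class{SpeciesSpec}.
#' @param duration recording length in seconds.
#' @param noiseDb signal-to-noise ratio in dB (default 30; \code{Inf} for
#'   no noise).
#' @param rate sampling rate in Hz.
#' @param shift analysis frame shift in seconds used to express the true
#'   boundaries on the standard analysis grid.
#' @param seed integer seed; same seed gives bit-identical audio.
#' @return list with elements \code{audio} (\linkS4class{AudioSignal})
#'   and \code{segments} (data.frame of true \code{startFrame} /
#'   \code{endFrame}, 0-based half-open on the analysis grid).
#' @export
synthRecording <- function(spec, duration = 3, noiseDb = 30, rate = 22050,
                           shift = 0.010, seed = 1) {
  stopifnot(methods::is(spec, "SpeciesSpec"))
  if (duration < spec@syllableDurationRange[2] + 0.1) {
    stop("duration must accommodate at least one syllable")
  }
  n <- round(duration * rate)
  withr::with_seed(.childSeed(seed, "rec"), {
    x <- numeric(n)
    onsets <- numeric(0)
    durs <- numeric(0)
    t0 <- 0.05 + stats::rexp(1, spec@syllableRate)
    repeat {
      d <- stats::runif(1, spec@syllableDurationRange[1],
                        spec@syllableDurationRange[2])
      if (t0 + d > duration - 0.05) break
      onsets <- c(onsets, t0)
      durs <- c(durs, d)
      t0 <- t0 + d + 0.12 + stats::rexp(1, spec@syllableRate)
    }
    for (s in seq_along(onsets)) {
      i0 <- round(onsets[s] * rate)
      ns <- round(durs[s] * rate)
      tt <- (seq_len(ns) - 1) / rate
      slope <- stats::runif(1, spec@chirpSlopeRange[1],
                            spec@chirpSlopeRange[2])
      syl <- numeric(ns)
      for (j in seq_along(spec@basisFreqs)) {
        f0 <- spec@basisFreqs[j]
        amp <- 1 / j
        phase <- stats::runif(1, 0, 2 * pi)
        syl <- syl + amp * sin(2 * pi * (f0 * tt + slope * tt^2 / 2) + phase)
      }
      syl <- syl * .tukeyEnvelope(ns, round(0.015 * rate))
      x[i0 + seq_len(ns)] <- x[i0 + seq_len(ns)] + syl
    }
    if (is.finite(noiseDb)) {
      p <- mean(x^2)
      if (p > 0) {
        x <- x + stats::rnorm(n, sd = sqrt(p / 10^(noiseDb / 10)))
      }
    }
  })
  segs <- data.frame(startFrame = as.integer(round(onsets / shift)),
                     endFrame = as.integer(round((onsets + durs) / shift)))
  list(audio = methods::new("AudioSignal", samples = x, sampleRate = rate),
       segments = segs)
}

#' Generate a labeled synthetic dataset
#'
#' The default scale (4 species x 30 recordings x 3 s at 30 dB SNR) is
#' the standard verification fixture for the end-to-end pipeline.
#'
#' @param nSpecies number of species (default 4).
#' @param recordingsPerSpecies recordings per species (default 30).
#' @param duration recording length in seconds (default 3).
#' @param noiseDb SNR in dB (default 30).
#' @param separation pairwise primary-frequency separation in Hz passed
#'   to [makeSpeciesSpecs()] (default: even spread).
#' @param rate sampling rate in Hz.
#' @param seed integer seed; generation is a pure function of the
#'   parameters and the seed.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
makeSyntheticDataset <- function(nSpecies = 4, recordingsPerSpecies = 30,
                                 duration = 3, noiseDb = 30,
                                 separation = NULL, rate = 22050,
                                 seed = 1) {
  specs <- makeSpeciesSpecs(nSpecies, separation = separation, seed = seed)
  recordings <- list()
  labels <- character(0)
  boundaries <- list()
  k <- 0L
  for (i in seq_along(specs)) {
    for (r in seq_len(recordingsPerSpecies)) {
      k <- k + 1L
      rec <- synthRecording(specs[[i]], duration = duration,
                            noiseDb = noiseDb, rate = rate,
                            seed = .childSeed(seed, "ds", i, r))
      recordings[[k]] <- rec$audio
      labels[k] <- specs[[i]]@name
      boundaries[[k]] <- rec$segments
    }
  }
  methods::new("SyntheticDataset", recordings = recordings, labels = labels,
               boundaries = boundaries, specs = specs,
               seed = as.integer(seed))
}

#' Write a dataset as WAV files plus a manifest CSV
#'
#' Mirrors the field-data input contract: one 16-bit PCM WAV per
#' recording and a \code{manifest.csv} with columns \code{path},
#' \code{species}; true boundaries go to \code{boundaries.csv}.
#'
#' @param dataset a \linkS4class{SyntheticDataset}.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset@recordings)
  paths <- sprintf("rec%04d.wav", seq_len(n))
  for (i in seq_len(n)) {
    writeAudio(dataset@recordings[[i]], file.path(dir, paths[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(path = paths, species = dataset@labels),
                   manifest, row.names = FALSE)
  bnd <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- dataset@boundaries[[i]]
    if (nrow(b) == 0) return(NULL)
    data.frame(path = paths[i], start_frame = b$startFrame,
               end_frame = b$endFrame)
  }))
  utils::write.csv(bnd, file.path(dir, "boundaries.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load recordings listed in a manifest CSV
#'
#' @param manifest path to a CSV with columns \code{path} (WAV file,
#'   relative to the manifest's directory) and \code{species}.
#' @param targetRate sampling rate passed to [readAudio()].
#' @return list with elements \code{recordings} and \code{labels},
#'   suitable for [kfoldEvaluate()] and [extractDatasetFeatures()].
#' @export
readDatasetManifest <- function(manifest, targetRate = 22050) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  recordings <- lapply(df$path, function(p) {
    readAudio(file.path(base, p), targetRate = targetRate)
  })
  list(recordings = recordings, labels = as.character(df$species))
}

#' Planted low-rank factorization fixture
#'
#' Builds V = W0 H0 under multiplicative log-normal noise, with W0
#' columns distinct Gaussian spectral bumps (L1-normalized) and H0 a
#' sparse non-negative activation matrix. With \code{noiseLevel = 0},
#' \code{klDivergence(V, W0, H0)} is exactly 0.
#'
#' @param nF,K,nT dimensions (K <= min(nF, nT)).
#' @param noiseLevel standard deviation of the log-normal noise exponent
#'   (default 0.05).
#' @param seed integer seed.
#' @return list with elements \code{V}, \code{W} (= W0) and \code{H}
#'   (= H0).
#' @export
plantedFactorization <- function(nF, K, nT, noiseLevel = 0.05, seed = 1) {
  stopifnot(K >= 1, K <= min(nF, nT))
  withr::with_seed(.childSeed(seed, "plant"), {
    centers <- seq(nF / (2 * K), nF - nF / (2 * K), length.out = K) +
      stats::runif(K, -0.1, 0.1) * nF / K
    width <- nF / (3 * K)
    W0 <- vapply(centers, function(c0) {
      w <- stats::dnorm(seq_len(nF), c0, width)
      w / sum(w)
    }, numeric(nF))
    H0 <- matrix(0, K, nT)
    for (j in seq_len(nT)) {
      active <- sample.int(K, 1 + stats::rbinom(1, min(2, K - 1), 0.4))
      H0[active, j] <- stats::rexp(length(active))
    }
    V <- (W0 %*% H0)
    if (noiseLevel > 0) {
      V <- V * exp(noiseLevel * stats::rnorm(length(V)))
    }
  })
  list(V = V, W = W0, H = H0)
}
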