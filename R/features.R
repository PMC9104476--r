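#' Canonical order of the 46-feature library
#'
#' The fixed order in which features are computed and reported; stepwise
#' selection breaks ties by this order.
#'
#' @return Character vector of the 46 feature names.
#' @export
feature_names <- function() {
  c("IEMG", "MAV", "MAV1", "MAV2", "SSI", "VAR", "RMS", "V2", "V3", "LOG",
    "WL", "AAC", "DASDV", "MFL", "MYOP", "WAMP", "MMAV", "ZC", "SSC",
    "TM3", "TM4", "TM5", "ASS", "MSR", "ASM", "Kurt", "Skew", "AFB",
    "MNP", "TTP", "MDF", "MNF", "PKF", "SM1", "SM2", "SM3", "FR", "MPD",
    "PSDd", "VCF", "HFD", "SaEn", "ApEn", "dPDR", "PSR", "AUC")
}

#' Threshold context for noise-referenced features
#'
#' MYOP uses a fixed amplitude threshold; WAMP and ZC use a threshold of
#' 0.3 times the SD of the subject's baseline-noise window, so "activity"
#' counts are referenced to each recording's own noise floor.
#'
#' @param sigma_noise SD of the baseline window (uV), > 0.
#' @param myop_threshold_uV MYOP amplitude threshold (uV), default 5.5.
#' @return List of class `threshold_ctx` with `sigma_noise`,
#'   `myop_threshold_uV` and `wamp_zc_threshold` (= 0.3 * sigma_noise).
#' @export
threshold_ctx <- function(sigma_noise, myop_threshold_uV = 5.5) {
  if (!is.finite(sigma_noise) || sigma_noise <= 0)
    stop("sigma_noise must be positive")
  structure(list(sigma_noise = sigma_noise,
                 myop_threshold_uV = myop_threshold_uV,
                 wamp_zc_threshold = 0.3 * sigma_noise),
            class = "threshold_ctx")
}

#' Amplitude-domain features of a burst window
#'
#' Computes the 21 amplitude/statistical features. With window x_1..x_N:
#' IEMG = sum |x|; MAV = IEMG/N; MAV1/MAV2 are weighted MAVs (weight 1 on the
#' central half, 0.5 or a linear ramp on the tails); SSI = sum x^2;
#' VAR = SSI/(N-1); RMS = V2 = sqrt(mean x^2); V3 = (mean |x|^3)^(1/3);
#' LOG = exp(mean log(|x| + eps)); TMk = |mean x^k| for k = 3,4,5;
#' ASS = sum sqrt(|x|); MSR = mean sqrt(|x|); ASM = sum |x|^p with exponent
#' p = 0.75 on the central 60% of samples and 0.5 on the tails; Kurt and Skew
#' are the (non-excess) Pearson moment ratios; AFB = max |x|; AUC is the
#' trapezoidal integral of |x| over time in uV s.
#'
#' @param x Numeric window (length >= 2), uV.
#' @param dt Sample interval in seconds (for AUC).
#' @return Named numeric vector of 21 features (MMAV excluded; see
#'   [compute_features()]).
#' @export
amplitude_features <- function(x, dt = 1e-3) {
  n <- length(x)
  if (n < 2) stop("window must have at least 2 samples")
  ax <- abs(x)
  i <- seq_len(n)
  eps <- 1e-12

  w1 <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 1, 0.5)
  w2 <- ifelse(i < 0.25 * n, 4 * i / n,
               ifelse(i > 0.75 * n, 4 * (i - n) / n, 1))
  ssi <- sum(x^2)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero-variance window: skewness/kurtosis undefined")
  p_asm <- ifelse(i >= 0.2 * n & i <= 0.8 * n, 0.75, 0.5)

  c(IEMG = sum(ax),
    MAV = mean(ax),
    MAV1 = mean(w1 * ax),
    MAV2 = mean(w2 * ax),
    SSI = ssi,
    VAR = ssi / (n - 1),
    RMS = sqrt(ssi / n),
    V2 = sqrt(mean(x^2)),
    V3 = mean(ax^3)^(1 / 3),
    LOG = exp(mean(log(ax + eps))),
    TM3 = abs(mean(x^3)),
    TM4 = abs(mean(x^4)),
    TM5 = abs(mean(x^5)),
    ASS = abs(sum(ax^0.5)),
    MSR = mean(ax^0.5),
    ASM = abs(sum(ax^p_asm)),
    Kurt = mean((x - m)^4) / m2^2,
    Skew = mean((x - m)^3) / m2^1.5,
    AFB = max(ax),
    AUC = sum((ax[-n] + ax[-1]) / 2) * dt)
}

#' Rate-of-change features
#'
#' With first differences D_i = x_(i+1) - x_i: WL = sum |D| (waveform length),
#' AAC = WL/N, DASDV = sqrt(sum D^2 / (N-1)), MFL = log10(sqrt(sum D^2)).
#' A constant window has WL = AAC = 0 and an undefined MFL (error).
#'
#' @param x Numeric window (length >= 2).
#' @return Named numeric vector: WL, AAC, DASDV, MFL.
#' @export
rate_features <- function(x) {
  n <- length(x)
  if (n < 2) stop("window must have at least 2 samples")
  d <- diff(x)
  ssd <- sum(d^2)
  if (ssd == 0) stop("constant window: MFL undefined")
  c(WL = sum(abs(d)),
    AAC = sum(abs(d)) / n,
    DASDV = sqrt(ssd / (n - 1)),
    MFL = log10(sqrt(ssd)))
}

#' Threshold-count features
#'
#' MYOP is the fraction of samples whose magnitude reaches the myopulse
#' threshold; WAMP counts consecutive-sample jumps of at least 0.3 sigma_noise;
#' ZC counts sign changes whose jump also reaches that threshold; SSC counts
#' interior slope-sign reversals (no threshold by default, configurable).
#'
#' @param x Numeric window (uV).
#' @param ctx A [threshold_ctx()].
#' @param ssc_threshold Threshold on the slope product for SSC (default 0).
#' @return Named numeric vector: MYOP, WAMP, ZC, SSC.
#' @export
threshold_features <- function(x, ctx, ssc_threshold = 0) {
  stopifnot(inherits(ctx, "threshold_ctx"))
  n <- length(x)
  d <- diff(x)
  thr <- ctx$wamp_zc_threshold
  slope_prod <- (x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n])
  c(MYOP = mean(abs(x) >= ctx$myop_threshold_uV),
    WAMP = sum(abs(d) >= thr),
    ZC = sum(x[-n] * x[-1] < 0 & abs(d) >= thr),
    SSC = sum(slope_prod > ssc_threshold))
}

#' Approximate entropy (ApEn)
#'
#' ApEn(m, r) = Phi_m - Phi_(m+1) with Phi_m the mean log of the fraction of
#' m-templates within Chebyshev tolerance r of each template, self-matches
#' included.
#'
#' @param x Numeric window, not constant.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default 0.2 * SD(x).
#' @return Scalar entropy.
#' @export
approx_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  if (!is.finite(r) || r <= 0)
    stop("tolerance r must be positive and finite (constant window?)")
  phi <- function(mm) {
    cnt <- cheb_counts(x, mm, r)
    n <- length(cnt)
    mean(log(cnt / n))
  }
  phi(m) - phi(m + 1)
}

#' Sample entropy (SampEn)
#'
#' SampEn(m, r) = -log(A / B) where B and A are the total numbers of
#' m- and (m+1)-template pairs within Chebyshev tolerance r, self-matches
#' excluded. Templates are restricted to the first N - m positions at both
#' lengths, per the standard definition.
#'
#' @inheritParams approx_entropy
#' @return Scalar entropy; `Inf` if no (m+1)-matches exist.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  if (!is.finite(r) || r <= 0)
    stop("tolerance r must be positive and finite (constant window?)")
  n <- length(x)
  b <- sum(cheb_counts(x, m, r, n_templates = n - m)) - (n - m)
  a <- sum(cheb_counts(x, m + 1, r, n_templates = n - m)) - (n - m)
  if (b == 0) return(Inf)
  if (a == 0) return(Inf)
  -log(a / b)
}

# Chebyshev-ball counts (incl. self-match) for the first `n_templates`
# m-length templates; the O(N^2) pair scan lives in compiled code.
cheb_counts <- function(x, m, r, n_templates = length(x) - m + 1) {
  cheb_counts_cpp(as.numeric(x), as.integer(m), r, as.integer(n_templates))
}

#' Higuchi fractal dimension
#'
#' Estimates the curve-length scaling exponent: for each lag k = 1..k_max the
#' mean normalized curve length L(k) over the k possible offsets is computed,
#' and HFD is the slope of log L(k) against log(1/k). A straight line has
#' HFD near 1; white noise approaches 2.
#'
#' @param x Numeric window, length > k_max.
#' @param k_max Maximum lag (default 128).
#' @return Scalar dimension estimate.
#' @export
higuchi_fd <- function(x, k_max = 128) {
  n <- length(x)
  if (n <= k_max) stop("window shorter than k_max")
  lk <- higuchi_lengths_cpp(as.numeric(x), as.integer(k_max))
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(k_max))))[[2]]
}

#' Complexity features: HFD, sample and approximate entropy
#'
#' @param x Numeric window, not constant, length > k_max.
#' @param k_max Higuchi maximum lag.
#' @param m Embedding dimension for the entropies.
#' @param r_factor Entropy tolerance as a multiple of SD(x).
#' @return Named numeric vector: HFD, SaEn, ApEn.
#' @export
complexity_features <- function(x, k_max = 128, m = 2, r_factor = 0.2) {
  r <- r_factor * stats::sd(x)
  if (!is.finite(r) || r <= 0)
    stop("entropy tolerance must be positive and finite (constant window?)")
  c(HFD = higuchi_fd(x, k_max),
    SaEn = sample_entropy(x, m, r),
    ApEn = approx_entropy(x, m, r))
}

#' One-sided periodogram power spectrum
#'
#' Mean-removed one-sided periodogram scaled so that the powers sum to the
#' mean-removed power of the window (Parseval), with frequency resolution
#' `sampling_rate / N`.
#'
#' @param x Numeric window.
#' @param sampling_rate Sampling rate in Hz.
#' @return List of class `power_spectrum`: `f` (Hz), `p` (power per bin).
#' @export
compute_spectrum <- function(x, sampling_rate) {
  n <- length(x)
  if (n < 2) stop("window must have at least 2 samples")
  xd <- x - mean(x)
  X <- stats::fft(xd)
  nh <- floor(n / 2)
  p <- Mod(X[1:(nh + 1)])^2 / n^2
  # double interior bins so one-sided power matches the two-sided total
  dbl <- 2:(if (n %% 2 == 0) nh else nh + 1)
  p[dbl] <- 2 * p[dbl]
  structure(list(f = (0:nh) * sampling_rate / n, p = p),
            class = "power_spectrum")
}

#' Welch power spectral density estimate
#'
#' Hann-windowed segments with 50% overlap; per-segment mean removal;
#' one-sided density scaling. Used for the MPD feature so that mean power
#' (periodogram) and mean power density (Welch) remain distinct estimators.
#'
#' @param x Numeric window.
#' @param sampling_rate Sampling rate, Hz.
#' @param nseg Segment length (default 256).
#' @return List: `f` (Hz), `psd` (power per Hz).
#' @export
welch_psd <- function(x, sampling_rate, nseg = 256) {
  n <- length(x)
  if (n < nseg) stop("window shorter than one Welch segment")
  step <- nseg / 2
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1)))
  u <- sum(w^2)
  nh <- nseg / 2
  acc <- numeric(nh + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    ps <- Mod(X[1:(nh + 1)])^2 / (sampling_rate * u)
    ps[2:nh] <- 2 * ps[2:nh]
    acc <- acc + ps
  }
  list(f = (0:nh) * sampling_rate / nseg, psd = acc / length(starts))
}

#' Frequency-domain features from a power spectrum
#'
#' Spectral moments SM_k = sum f^k P; MNP = mean bin power; TTP = SM0;
#' MNF = SM1/SM0; MDF = first frequency where cumulative power reaches half
#' of TTP; PKF = frequency of the largest bin (earliest on ties);
#' FR = power below MNF over power above MNF; MPD = mean Welch PSD;
#' PSDd = sqrt(SM2 SM0)/SM1 (>= 1); VCF = SM2/SM0 - (SM1/SM0)^2 (>= 0);
#' dPDR = max power over minimum power within 20-400 Hz; PSR = power within
#' +/- 20 bins of the peak over TTP.
#'
#' @param spec A `power_spectrum` from [compute_spectrum()].
#' @param x Original window (for the Welch-based MPD); may be `NULL`, in
#'   which case MPD is `NA`.
#' @param sampling_rate Sampling rate, Hz.
#' @param band Band for the dPDR minimum, Hz.
#' @param psr_halfwidth Peak neighbourhood half width in bins (default 20).
#' @return Named numeric vector of 14 spectral features.
#' @export
spectral_features <- function(spec, x = NULL, sampling_rate = 1000,
                              band = c(20, 400), psr_halfwidth = 20) {
  f <- spec$f; p <- spec$p
  sm0 <- sum(p)
  if (sm0 <= 0) stop("zero total power")
  sm1 <- sum(f * p); sm2 <- sum(f^2 * p); sm3 <- sum(f^3 * p)
  mnf <- sm1 / sm0
  mdf <- f[which(cumsum(p) >= sm0 / 2)[1]]
  jpk <- which.max(p)
  inb <- f >= band[1] & f <= band[2]
  nb <- abs(seq_along(p) - jpk) <= psr_halfwidth
  mpd <- if (is.null(x)) NA_real_ else mean(welch_psd(x, sampling_rate)$psd)
  c(MNP = mean(p),
    TTP = sm0,
    MDF = mdf,
    MNF = mnf,
    PKF = f[jpk],
    SM1 = sm1, SM2 = sm2, SM3 = sm3,
    FR = sum(p[f < mnf]) / sum(p[f > mnf]),
    MPD = mpd,
    PSDd = sqrt(sm2 / sm0) / (sm1 / sm0),
    VCF = sm2 / sm0 - (sm1 / sm0)^2,
    dPDR = max(p) / max(min(p[inb]), 1e-12),
    PSR = sum(p[nb]) / sm0)
}

#' Compute the full 46-feature vector of one window
#'
#' Runs all feature groups on a single-channel window and returns the
#' features in the canonical [feature_names()] order. MMAV is the
#' centre-weighted MAV (identical in form to MAV1, kept under its own name
#' as the library lists all three; selection handles the collinearity).
#'
#' @param x Numeric window (1500 samples at 1 kHz in the standard pipeline).
#' @param sampling_rate Sampling rate, Hz.
#' @param ctx A [threshold_ctx()] built from the recording's baseline noise.
#' @param ssc_threshold SSC slope-product threshold (default 0).
#' @return Named numeric vector, length 46, all finite (error otherwise).
#' @export
compute_features <- function(x, sampling_rate, ctx, ssc_threshold = 0) {
  amp <- amplitude_features(x, dt = 1 / sampling_rate)
  rate <- rate_features(x)
  thr <- threshold_features(x, ctx, ssc_threshold)
  cmplx <- complexity_features(x)
  spec <- compute_spectrum(x, sampling_rate)
  sp <- spectral_features(spec, x, sampling_rate)
  v <- c(amp, rate, thr, MMAV = unname(amp["MAV1"]), cmplx, sp)
  v <- v[feature_names()]
  bad <- !is.finite(v)
  if (any(bad))
    stop("non-finite feature(s): ", paste(names(v)[bad], collapse = ", "))
  v
}

#' Build one observation's feature vector from a left/right window pair
#'
#' Features are computed per channel and combined: `mode = "mean"` averages
#' the two channels' features (default); `mode = "concat"` returns 92 values
#' with `_L`/`_R` suffixes.
#'
#' @param left,right Numeric windows of equal length.
#' @param ctx_left,ctx_right Per-channel [threshold_ctx()].
#' @param sampling_rate Sampling rate, Hz.
#' @param mode `"mean"` or `"concat"`.
#' @return Named numeric vector (46 or 92 values).
#' @export
build_feature_vector <- function(left, right, ctx_left, ctx_right,
                                 sampling_rate = 1000,
                                 mode = c("mean", "concat")) {
  mode <- match.arg(mode)
  if (length(left) != length(right)) stop("channel window lengths differ")
  fl <- compute_features(left, sampling_rate, ctx_left)
  fr <- compute_features(right, sampling_rate, ctx_right)
  if (mode == "mean") return((fl + fr) / 2)
  out <- c(fl, fr)
  names(out) <- c(paste0(names(fl), "_L"), paste0(names(fr), "_R"))
  out
}

#' Extract the feature matrix of a cohort
#'
#' Preprocesses every recording (filter, localize, window) and computes one
#' feature row per window: a `burst` row and a `baseline` row per recording.
#' Threshold features are referenced to each recording's own baseline SD.
#' Warnings about late bursts whose window touches the baseline window are
#' collected and reported once.
#'
#' @param cohort Result of [generate_cohort()] (or an equivalent list with
#'   `recordings` and `metadata`).
#' @param spec A [filter_spec()].
#' @param mode Channel combination mode, see [build_feature_vector()].
#' @return data.frame: recording, subject, task, volume_mL, kind
#'   (burst/baseline) and the feature columns.
#' @export
extract_cohort_features <- function(cohort, spec = filter_spec(),
                                    mode = "mean") {
  recs <- cohort$recordings
  meta <- cohort$metadata
  h <- design_bandpass(spec, recs[[1]]$sampling_rate_hz)
  n_overlap <- 0L
  rows <- vector("list", 2L * length(recs))
  for (i in seq_along(recs)) {
    pr <- withCallingHandlers(
      process_recording(recs[[i]], h = h),
      warning = function(w) {
        if (grepl("overlaps the baseline", conditionMessage(w))) {
          n_overlap <<- n_overlap + 1L
          invokeRestart("muffleWarning")
        }
      })
    cl <- threshold_ctx(pr$sigma_noise[["left"]])
    cr <- threshold_ctx(pr$sigma_noise[["right"]])
    fs <- recs[[i]]$sampling_rate_hz
    fb <- build_feature_vector(pr$burst$left, pr$burst$right, cl, cr, fs, mode)
    fn <- build_feature_vector(pr$baseline$left, pr$baseline$right,
                               cl, cr, fs, mode)
    base <- meta[i, c("recording", "subject", "task", "volume_mL")]
    rows[[2 * i - 1]] <- cbind(base, kind = "burst", as.data.frame(t(fb)))
    rows[[2 * i]] <- cbind(base, kind = "baseline", as.data.frame(t(fn)))
  }
  if (n_overlap > 0)
    message(n_overlap, " recording(s) had a late burst overlapping the ",
            "baseline window")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
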