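#' Segment cells in a label-free (phase-like) frame
#'
#' Non-local-means denoising (noise SD auto-estimated by the Immerkaer
#' pseudo-residual method; patch 7 px, search 21 px), triangle
#' auto-threshold, opening/closing (2 px disk) and hole filling.
#'
#' @param frame single-channel 2D numeric matrix.
#' @param smoothing_factor scales the denoising strength (ImageJ-style
#'   factor; 1 = default).
#' @param min_size minimum particle size kept, pixels (0 keeps all).
#' @return logical cell mask; a degenerate (single-valued) frame returns an
#'   empty mask with attribute `degenerate = TRUE`.
#' @export
segment_cells_phase <- function(frame, smoothing_factor = 1, min_size = 0) {
  gp_validate(is.matrix(frame), "frame must be a 2D matrix")
  img <- norm01(frame)
  sigma <- estimate_noise_sd(img)
  den <- if (sigma > 0)
    nlm_denoise_cpp(img, sigma, h = 0.6 * smoothing_factor * sigma + 1e-12,
                    patch_radius = 3L, search_radius = 10L)
  else img
  lev <- tryCatch(triangle_threshold(hist256(den)),
                  gelplate_degenerate = function(e) NULL)
  if (is.null(lev)) {
    out <- matrix(FALSE, nrow(frame), ncol(frame))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  m <- apply_level(den, lev)
  m <- EBImage::opening(m * 1, brush5()) > 0
  m <- EBImage::closing(m * 1, brush5()) > 0
  m <- EBImage::fillHull(m * 1) > 0
  if (min_size > 0) {
    lab <- EBImage::bwlabel(m * 1)
    keep <- which(tabulate(lab[lab > 0]) >= min_size)
    m <- matrix(lab %in% keep, nrow(m), ncol(m)) & m
  }
  matrix(m, nrow(frame), ncol(frame))
}

# Immerkaer fast noise estimate from the 3x3 Laplacian pseudo-residual
estimate_noise_sd <- function(img) {
  M <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  r <- as.matrix(EBImage::filter2(EBImage::Image(img), M))
  interior <- r[2:(nrow(r) - 1), 2:(ncol(r) - 1)]
  sqrt(pi / 2) * mean(abs(interior)) / 6
}

#' Confluency trace from a time-lapse
#'
#' Percent covered area per frame via [segment_cells_phase()].  Frames above
#' the review threshold (30% by default, where automatic segmentation of
#' dense fields degrades) are flagged for review, not corrected.
#'
#' @param frames an [image_stack()] with axes (t, y, x), a 3D array, or a
#'   list of matrices.
#' @param review_threshold percent confluency above which frames are flagged.
#' @param ... forwarded to [segment_cells_phase()].
#' @return A `confluency_trace`: `times_h`, `raw_pct`, `flags`
#'   (`ok`/`review`); smoothing and normalization are added by
#'   [smooth_trace()] and [normalize_trace()].
#' @export
confluency_trace <- function(frames, review_threshold = 30, ...) {
  if (inherits(frames, "image_stack")) {
    st <- canonical_stack(frames)
    arr <- st$pixels
    dt <- if (is.finite(st$time_step_min)) st$time_step_min / 60 else 1
    frames <- lapply(seq_len(dim(arr)[1]), function(t)
      array(arr[t, , ], dim(arr)[2:3]))
  } else if (is.array(frames) && length(dim(frames)) == 3) {
    arr <- frames; dt <- 1
    frames <- lapply(seq_len(dim(arr)[1]), function(t)
      array(arr[t, , ], dim(arr)[2:3]))
  } else dt <- 1
  gp_validate(length(frames) >= 1, "need at least one frame")
  raw <- vapply(frames, function(f)
    100 * mean(segment_cells_phase(f, ...)), 0)
  structure(list(times_h = (seq_along(raw) - 1) * dt, raw_pct = raw,
                 smoothed_pct = NULL, normalized = NULL,
                 flags = ifelse(raw > review_threshold, "review", "ok")),
            class = "confluency_trace")
}

#' Smooth a confluency trace
#'
#' Centred moving average (default window 4, shrinking at the edges).
#'
#' @param trace a `confluency_trace`.
#' @param window moving-average window, frames.
#' @return the trace with `smoothed_pct` filled in.
#' @export
smooth_trace <- function(trace, window = 4) {
  gp_validate(inherits(trace, "confluency_trace"), "not a confluency_trace")
  trace$smoothed_pct <- moving_avg(trace$raw_pct, window)
  trace
}

#' Normalize a confluency trace to its initial value
#'
#' @param trace a smoothed `confluency_trace` (smoothing is applied with the
#'   default window if missing).
#' @return the trace with `normalized` filled in (`normalized[1] == 1`).
#' @export
normalize_trace <- function(trace) {
  gp_validate(inherits(trace, "confluency_trace"), "not a confluency_trace")
  if (is.null(trace$smoothed_pct)) trace <- smooth_trace(trace)
  if (trace$smoothed_pct[1] <= 0)
    gp_stop("initial confluency is zero; cannot normalize",
            "gelplate_normalization")
  trace$normalized <- trace$smoothed_pct / trace$smoothed_pct[1]
  trace
}

#' @export
print.confluency_trace <- function(x, ...) {
  cat(sprintf("<confluency_trace> %d frames, %.1f -> %.1f%% raw (%d flagged)\n",
              length(x$raw_pct), x$raw_pct[1],
              x$raw_pct[length(x$raw_pct)], sum(x$flags == "review")))
  invisible(x)
}

#' Four-parameter log-logistic dose-response fit (IC50)
#'
#' Fits `R(d) = bottom + (top - bottom) / (1 + (d / IC50)^hill)` by
#' Levenberg-Marquardt least squares; confidence intervals come from a
#' seeded residual bootstrap.  Dose 0 (vehicle) is mapped half a decade
#' below the lowest nonzero dose for fitting.
#'
#' @param doses dose vector (>= 4 distinct values; may include 0).
#' @param responses responses, same length (positive).
#' @param n_boot bootstrap resamples for the IC50 CI.
#' @param seed bootstrap seed.
#' @return A `dose_response_fit`: `ic50`, `hill`, `top`, `bottom`,
#'   `converged`, `ic50_ci`, `per_dose` summary.
#' @export
fit_dose_response <- function(doses, responses, n_boot = 200, seed = 1) {
  gp_validate(length(doses) == length(responses),
              "doses and responses differ in length")
  gp_validate(length(unique(doses)) >= 4, "need >= 4 distinct doses")
  gp_validate(all(responses > 0), "responses must be positive")
  nz <- doses[doses > 0]
  gp_validate(length(nz) > 0, "need nonzero doses")
  d <- ifelse(doses == 0, min(nz) / sqrt(10), doses)
  per <- aggregate(responses, list(dose = doses), function(v)
    c(mean = mean(v), sem = sd(v) / sqrt(length(v))))
  per_dose <- data.frame(dose = per$dose, mean = per$x[, "mean"],
                         sem = per$x[, "sem"])
  flat <- diff(range(responses)) < 1e-10 * max(abs(responses))
  bad <- function() structure(list(ic50 = NA_real_, hill = NA_real_,
                                   top = NA_real_, bottom = NA_real_,
                                   converged = FALSE, ic50_ci = c(NA, NA),
                                   per_dose = per_dose),
                              class = "dose_response_fit")
  if (flat) return(bad())
  fit1 <- function(y) {
    st <- list(top = max(y), bottom = min(y),
               lic50 = mean(log(d)), hill = 1)
    f <- tryCatch(minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(hill * (log(d) - lic50))),
      start = st,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) return(NULL)
    cf <- coef(f)
    list(ic50 = exp(cf[["lic50"]]), hill = cf[["hill"]],
         top = cf[["top"]], bottom = cf[["bottom"]],
         fitted = stats::fitted(f), resid = stats::resid(f))
  }
  base <- fit1(responses)
  if (is.null(base) || !is.finite(base$ic50) || base$ic50 <= 0) return(bad())
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        yb <- base$fitted + sample(base$resid, replace = TRUE)
        fb <- fit1(pmax(yb, 1e-9))
        if (is.null(fb)) NA_real_ else fb$ic50
      }, 0)
    })
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 20)
      ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  structure(list(ic50 = base$ic50, hill = base$hill, top = base$top,
                 bottom = base$bottom, converged = TRUE, ic50_ci = ci,
                 per_dose = per_dose),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) cat("<dose_response_fit> not converged\n")
  else cat(sprintf(
    "<dose_response_fit> IC50 = %.3g (95%% CI %.3g-%.3g), hill = %.2f\n",
    x$ic50, x$ic50_ci[1], x$ic50_ci[2], x$hill))
  invisible(x)
}

#' Logistic growth-rate readout from two confluency measurements
#'
#' For logistic growth the log-odds of the covered fraction increases
#' linearly with time at the growth rate, so
#' `(logit(c_end) - logit(c_start)) / elapsed frames` recovers the per-frame
#' rate from the two endpoint measurements alone.  Unlike the raw endpoint
#' ratio, this readout is proportional to the growth rate in every growth
#' regime, so a Hill-suppressed rate stays exactly log-logistic in dose.
#'
#' @param c_start,c_end covered-area fractions in (0, 1).
#' @param n_frames total frames spanned (rate is per frame).
#' @return per-frame logistic growth rate (floored at 0).
#' @export
logistic_rate <- function(c_start, c_end, n_frames) {
  gp_validate(n_frames >= 2, "need at least 2 frames")
  cl <- function(p) min(max(p, 1e-4), 1 - 1e-4)
  logit <- function(p) log(p / (1 - p))
  max((logit(cl(c_end)) - logit(cl(c_start))) / (n_frames - 1), 0)
}

#' Seeded synthetic dose-response experiment
#'
#' Generates one growth movie per dose x replicate, measures initial and
#' final confluency with [segment_cells_phase()], converts to growth-rate
#' responses with [logistic_rate()] and fits the four-parameter log-logistic
#' model.
#'
#' @param seed experiment seed (drives every movie).
#' @param doses dose grid (>= 4 distinct values).
#' @param n_replicates movies per dose.
#' @param ic50_true,hill,r0,n_frames forwarded to
#'   [generate_confluency_movie()].
#' @param n_boot bootstrap resamples for the fit CI.
#' @return list with `fit` (a `dose_response_fit`), `responses`
#'   (data.frame dose/replicate/rate) and `ic50_true`.
#' @export
run_ic50_experiment <- function(seed, doses = c(0, 4.5, 9, 18, 36, 72),
                                n_replicates = 12, ic50_true = 18, hill = 2,
                                r0 = 0.04, n_frames = 49, n_boot = 0) {
  seeds <- matrix(derive_seeds(seed, length(doses) * n_replicates),
                  length(doses), n_replicates)
  rows <- list()
  for (i in seq_along(doses)) for (j in seq_len(n_replicates)) {
    mv <- generate_confluency_movie(doses[i], ic50_true = ic50_true,
                                    hill = hill, r0 = r0,
                                    n_frames = n_frames, seed = seeds[i, j])
    arr <- mv$stack$pixels
    c1 <- mean(segment_cells_phase(array(arr[1, , ], dim(arr)[2:3])))
    c2 <- mean(segment_cells_phase(array(arr[n_frames, , ],
                                         dim(arr)[2:3])))
    rows[[length(rows) + 1]] <- data.frame(
      dose = doses[i], replicate = j,
      rate = logistic_rate(c1, c2, n_frames))
  }
  resp <- do.call(rbind, rows)
  fit <- fit_dose_response(resp$dose, pmax(resp$rate, 1e-6),
                           n_boot = n_boot, seed = seed)
  list(fit = fit, responses = resp, ic50_true = ic50_true)
}
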