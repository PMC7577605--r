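# Low-level visual properties of stimulus clips: HSL brightness/hue/
# saturation, RMS contrast, block-matching motion energy, 2x2 factorial
# condition tests, and the visually-most-deviant-block removal rule.

#' Construct a video clip
#'
#' @param frames Numeric 4D array (height x width x 3 x n_frames), RGB in
#'   0-255, or a list of height x width x 3 arrays.
#' @param fps Frame rate (informational).
#' @return Object of class `video_clip`.
#' @export
video_clip <- function(frames, fps = 25) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    stopifnot(length(d) == 3L, d[3] == 3L,
              all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    arr <- array(unlist(frames), dim = c(d, length(frames)))
  } else {
    arr <- frames
    stopifnot(length(dim(arr)) == 4L, dim(arr)[3] == 3L)
  }
  if (dim(arr)[4] < 1L) stop("clip needs at least one frame")
  structure(list(frames = arr, fps = fps), class = "video_clip")
}

# RGB (0-255) planes -> list(h degrees, s, l), all same shape. Hue is NA for
# achromatic pixels.
.rgb_to_hsl <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- rep(NA_real_, length(r))
  rr <- d > 0 & mx == r
  gg <- d > 0 & mx == g & !rr
  bb <- d > 0 & mx == b & !rr & !gg
  h[rr] <- 60 * (((g[rr] - b[rr]) / d[rr]) %% 6)
  h[gg] <- 60 * ((b[gg] - r[gg]) / d[gg] + 2)
  h[bb] <- 60 * ((r[bb] - g[bb]) / d[bb] + 4)
  list(h = h, s = s, l = l)
}

.circular_mean_deg <- function(h) {
  h <- h[!is.na(h)]
  if (!length(h)) return(NA_real_)
  a <- h * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
}

#' HSL properties of a clip
#'
#' Per pixel standard RGB to HSL conversion; per frame, brightness is the
#' mean lightness L, saturation the mean S, and hue the circular mean of H
#' in degrees (achromatic pixels excluded); clip values are frame means.
#' Hue uses a circular mean, which avoids the 359-vs-1 degree artifact of a
#' naive average.
#'
#' @param clip A [video_clip()].
#' @return List with `brightness`, `hue`, `saturation` (hue NA for an
#'   entirely achromatic clip).
#' @export
hsl_properties <- function(clip) {
  stopifnot(inherits(clip, "video_clip"))
  nf <- dim(clip$frames)[4]
  per <- vapply(seq_len(nf), function(f) {
    fr <- clip$frames[, , , f]
    hsl <- .rgb_to_hsl(fr[, , 1], fr[, , 2], fr[, , 3])
    c(brightness = mean(hsl$l), hue = .circular_mean_deg(hsl$h),
      saturation = mean(hsl$s))
  }, numeric(3))
  hue <- per["hue", ]
  list(brightness = mean(per["brightness", ]),
       hue = if (all(is.na(hue))) NA_real_ else .circular_mean_deg(hue),
       saturation = mean(per["saturation", ]))
}

#' Root-mean-square contrast of a clip
#'
#' Per frame, the population SD of the grayscale intensity (Rec.601
#' luminance 0.299 R + 0.587 G + 0.114 B, normalized to 0-1), averaged over
#' frames.
#'
#' @param clip A [video_clip()].
#' @return Mean RMS contrast.
#' @export
rms_contrast <- function(clip) {
  stopifnot(inherits(clip, "video_clip"))
  nf <- dim(clip$frames)[4]
  mean(vapply(seq_len(nf), function(f) {
    fr <- clip$frames[, , , f]
    lum <- (0.299 * fr[, , 1] + 0.587 * fr[, , 2] + 0.114 * fr[, , 3]) / 255
    sqrt(mean((lum - mean(lum))^2))
  }, numeric(1)))
}

.gray_frames <- function(clip) {
  nf <- dim(clip$frames)[4]
  lapply(seq_len(nf), function(f) {
    fr <- clip$frames[, , , f]
    0.299 * fr[, , 1] + 0.587 * fr[, , 2] + 0.114 * fr[, , 3]
  })
}

#' Block-matching motion energy
#'
#' Exhaustive-search block matching between consecutive grayscale frames:
#' the current frame is tiled into `block_size` x `block_size` blocks and
#' each block's best match (minimum sum of absolute differences) is sought
#' in the next frame within +-`search_px` pixels; ties prefer the smaller
#' displacement (then lexicographic order). The clip value is the mean
#' motion-vector magnitude in px/frame over blocks and frame pairs.
#'
#' @param clip A [video_clip()] with >= 2 frames.
#' @param block_size Block side in pixels (default 16; clipped to the frame).
#' @param search_px Search range in pixels (default 8).
#' @return Mean motion magnitude (px/frame).
#' @export
motion_energy <- function(clip, block_size = 16L, search_px = 8L) {
  stopifnot(inherits(clip, "video_clip"))
  gf <- .gray_frames(clip)
  if (length(gf) < 2L) stop("motion estimation needs at least 2 frames")
  h <- nrow(gf[[1]]); w <- ncol(gf[[1]])
  bs <- min(block_size, h, w)
  ys <- seq(1L, h - bs + 1L, by = bs)
  xs <- seq(1L, w - bs + 1L, by = bs)
  offs <- expand.grid(dy = -search_px:search_px, dx = -search_px:search_px)
  offs$mag <- sqrt(offs$dy^2 + offs$dx^2)
  offs <- offs[order(offs$mag, offs$dy, offs$dx), ]
  mags <- c()
  for (f in seq_len(length(gf) - 1L)) {
    cur <- gf[[f]]; nxt <- gf[[f + 1L]]
    for (y in ys) for (x in xs) {
      blk <- cur[y:(y + bs - 1L), x:(x + bs - 1L)]
      best <- Inf; best_mag <- 0
      for (o in seq_len(nrow(offs))) {
        y2 <- y + offs$dy[o]; x2 <- x + offs$dx[o]
        if (y2 < 1L || x2 < 1L || y2 + bs - 1L > h || x2 + bs - 1L > w) next
        sad <- sum(abs(blk - nxt[y2:(y2 + bs - 1L), x2:(x2 + bs - 1L)]))
        if (sad < best - 1e-9) { best <- sad; best_mag <- offs$mag[o] }
      }
      mags <- c(mags, best_mag)
    }
  }
  mean(mags)
}

#' Compute all five properties for one clip
#'
#' @param clip A [video_clip()].
#' @return Named list: brightness, contrast, hue, saturation, motion
#'   (motion NA for single-frame clips).
#' @export
clip_properties <- function(clip) {
  hsl <- hsl_properties(clip)
  list(brightness = hsl$brightness, contrast = rms_contrast(clip),
       hue = hsl$hue, saturation = hsl$saturation,
       motion = if (dim(clip$frames)[4] >= 2L) motion_energy(clip) else NA_real_)
}

.cond_factors <- function(condition) {
  data.frame(face = factor(ifelse(condition %in% c("CF", "HeF"), "F", "O")),
             species = factor(ifelse(condition %in% c("CF", "CO"), "C", "He")))
}

#' 2 x 2 factorial ANOVA on a block property
#'
#' Face (F vs O) by species (conspecific vs heterospecific) ANOVA on the
#' chosen property of a block-property table.
#'
#' @param table Data frame with `condition` and the property column.
#' @param property Property column name.
#' @return Data frame with `effect`, `F`, `p` for both main effects and the
#'   interaction.
#' @export
property_anova_2x2 <- function(table, property) {
  if (!property %in% names(table)) stop("unknown property: ", property)
  df <- cbind(.cond_factors(table$condition), beta = table[[property]])
  if (nlevels(df$face) < 2L || nlevels(df$species) < 2L)
    stop("both factors need both levels")
  res <- roi_factorial_anova(df, factors = c("face", "species"))
  data.frame(effect = res$effect, F = res$F, p = res$p)
}

#' Remove the visually most deviant block per condition and run
#'
#' For each of brightness, contrast, hue and saturation, blocks are ranked
#' within each condition and run by their contribution to the
#' cross-condition difference: the block value's deviation from the mean of
#' the other conditions in the same run, signed toward the condition's own
#' deviation (`mode = "aligned"`, the default) or in absolute value
#' (`mode = "absolute"`). Ranks are summed over the four properties and the
#' top-ranked block per condition and run is removed; ties break toward the
#' lowest block index.
#'
#' @param table Block-property table (`run`, `block`, `condition`,
#'   properties).
#' @param properties Properties entering the ranking.
#' @param mode `"aligned"` or `"absolute"`.
#' @return List with `table` (reduced) and `removed` (run, condition, block).
#' @export
deviant_block_removal <- function(table,
                                  properties = c("brightness", "contrast",
                                                 "hue", "saturation"),
                                  mode = c("aligned", "absolute")) {
  mode <- match.arg(mode)
  key <- interaction(table$run, table$condition, drop = TRUE)
  if (any(tabulate(key) < 2L)) stop("need >= 2 blocks per condition per run")
  total_rank <- numeric(nrow(table))
  for (p in properties) {
    v <- table[[p]]
    contrib <- numeric(nrow(table))
    for (r in unique(table$run)) {
      in_run <- table$run == r
      for (cond in unique(table$condition[in_run])) {
        rows <- which(in_run & table$condition == cond)
        others <- which(in_run & table$condition != cond)
        m_other <- mean(v[others])
        dev <- v[rows] - m_other
        contrib[rows] <- if (mode == "aligned")
          dev * sign(mean(dev) + 1e-300) else abs(dev)
      }
    }
    for (g in levels(key)) {
      rows <- which(key == g)
      total_rank[rows] <- total_rank[rows] + rank(contrib[rows], ties.method = "min")
    }
  }
  removed <- do.call(rbind, lapply(levels(key), function(g) {
    rows <- which(key == g)
    top <- rows[order(-total_rank[rows], table$block[rows])][1L]
    table[top, c("run", "condition", "block")]
  }))
  keep <- !(paste(table$run, table$block) %in% paste(removed$run, removed$block))
  list(table = table[keep, , drop = FALSE], removed = removed)
}
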