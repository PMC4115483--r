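#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: phantom generation,
#' preprocessing, contour tracking, measurement and acoustics.
#'
#' @param seed Master integer seed; every random step derives its own
#'   sub-seed from it, so a run is fully reproducible.
#' @param vowels Vowel labels to process (subset of the
#'   [default_archetypes()] names).
#' @param n_frames Frames generated per vowel.
#' @param jitter Maximum per-frame tongue perturbation in px.
#' @param size Phantom frame side length in px.
#' @param blur_sigma,noise_sd Phantom degradation parameters.
#' @param resolution Pixels per millimetre.
#' @param preprocess A [preprocess_config()].
#' @param snake A [snake_config()].
#' @param formant_kwargs Named list of overrides passed to
#'   [formant_settings_for()] (e.g. `list(window = 0.025)`).
#' @param f0_male,f0_female Fundamental frequencies (Hz) used when
#'   synthesizing the audio for each gender.
#' @param audio_duration Duration (s) of each synthesized vowel.
#' @param tables_only If `TRUE`, [run_pipeline()] skips image and audio
#'   processing and computes summaries and correlations directly from the
#'   reference tables shipped with the package.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, vowels = names(default_archetypes()),
                            n_frames = 7, jitter = 1, size = 256,
                            blur_sigma = 0.5, noise_sd = 4,
                            resolution = 1.057,
                            preprocess = preprocess_config(),
                            snake = snake_config(),
                            formant_kwargs = list(),
                            f0_male = 120, f0_female = 210,
                            audio_duration = 0.5, tables_only = FALSE) {
  stopifnot(n_frames >= 1, length(vowels) >= 1,
            inherits(preprocess, "preprocess_config"),
            inherits(snake, "snake_config"))
  structure(list(seed = as.integer(seed), vowels = vowels,
                 n_frames = as.integer(n_frames), jitter = jitter,
                 size = as.integer(size), blur_sigma = blur_sigma,
                 noise_sd = noise_sd, resolution = resolution,
                 preprocess = preprocess, snake = snake,
                 formant_kwargs = formant_kwargs,
                 f0_male = f0_male, f0_female = f0_female,
                 audio_duration = audio_duration,
                 tables_only = isTRUE(tables_only)),
            class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are ignored.
#' Recognized keys are the scalar arguments of [pipeline_config()] plus
#' dotted preprocessing and snake keys, e.g. `preprocess.open_radius = 1`,
#' `snake.alpha = 1.2`, `snake.max_iter = 200`. `vowels` takes a
#' comma-separated list.
#'
#' @param path Path to the configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed config line: ", lines[which(bad)[1]], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  if (anyDuplicated(keys))
    stop("duplicate config key: ", keys[duplicated(keys)][1], call. = FALSE)
  num <- function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("non-numeric config value: ", v, call. = FALSE)
    x
  }
  args <- list(); pre <- list(); snk <- list(); wts <- list()
  scalar_keys <- c("seed", "n_frames", "jitter", "size", "blur_sigma",
                   "noise_sd", "resolution", "f0_male", "f0_female",
                   "audio_duration")
  weight_keys <- c("alpha", "beta", "gamma", "sigma")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% scalar_keys) args[[k]] <- num(v)
    else if (k == "vowels") args$vowels <- trimws(strsplit(v, ",")[[1]])
    else if (k == "tables_only") args$tables_only <- tolower(v) %in% c("true", "1", "yes")
    else if (startsWith(k, "preprocess.")) pre[[sub("^preprocess\\.", "", k)]] <- num(v)
    else if (startsWith(k, "snake.")) {
      sk <- sub("^snake\\.", "", k)
      if (sk %in% weight_keys) wts[[sk]] <- num(v)
      else if (sk == "stop_rule") snk$stop_rule <- v
      else snk[[sk]] <- num(v)
    }
    else stop("unknown config key: ", k, call. = FALSE)
  }
  if (length(pre)) args$preprocess <- do.call(preprocess_config, pre)
  if (length(wts) || length(snk)) {
    snk$weights <- do.call(energy_weights, wts)
    args$snake <- do.call(snake_config, snk)
  }
  do.call(pipeline_config, args)
}

#' Neutral higher formant frequencies
#'
#' Nominal F3--F5 of a neutral vocal tract, used to complete a synthesized
#' vowel spectrum when only F1 and F2 are specified; LPC analysis assumes a
#' full set of resonances below the analysis ceiling.
#'
#' @param gender `"M"` or `"F"`.
#' @return Numeric vector `c(F3, F4, F5)` in Hz.
#' @export
neutral_upper_formants <- function(gender = c("M", "F")) {
  gender <- match.arg(gender)
  if (gender == "M") c(2500, 3500, 4500) else c(2900, 4000, 4900)
}

# Derive a reproducible sub-seed (< 2^31) from the master seed and a label.
.sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.double(seed) * 7919 + h * 104729) %% 2147483647
}

#' Preprocess and track one frame
#'
#' Runs the full per-frame chain: cavity threshold and opening, component
#' labelling and filtering, oral-cavity selection, initial-point sampling and
#' the greedy active contour.
#'
#' @param frame A [vt_frame()].
#' @param plane A [palatal_plane()] used to reject the nasal cavity.
#' @param jaw_mask Optional 0/1 jaw mask for [filter_segments()].
#' @param pre A [preprocess_config()].
#' @param snake A [snake_config()].
#' @return A list with `state` (final `snake_state`), `contour` (tracked
#'   tongue points), `init` (`initial_points`), `cavity` (selected 0/1 mask)
#'   and `converged`.
#' @export
track_frame <- function(frame, plane, jaw_mask = NULL,
                        pre = preprocess_config(), snake = snake_config()) {
  mask <- extract_cavity_mask(frame, pre)
  segs <- filter_segments(label_segments(mask), jaw_mask, pre)
  cavity <- select_cavity_component(segs, plane)
  init <- select_initial_points(cavity, pre$n_upper, pre$n_lower,
                                pre$close_radius)
  state <- run_snake(frame, init, snake)
  list(state = state, contour = snake_contour(state), init = init,
       cavity = cavity, converged = state$converged)
}

.measurements_df <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(vowel = r$vowel, frame_index = r$m$frame_index,
               ttcl = r$m$ttcl, tbcl = r$m$tbcl, la = r$m$la)))
}

.summaries_df <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(vowel = s$vowel, gender = s$gender, parameter = s$parameter,
               n = s$n, mean = s$mean, std = s$std, variance = s$variance)))
}

#' Run the full vocal-tract analysis pipeline
#'
#' Phantom mode (the default): for every requested vowel, renders a jittered
#' sequence of midsagittal phantom frames, tracks the tongue contour in each,
#' measures TTCL, TBCL and LA against the known palate trace and lip
#' landmarks, and summarizes per vowel. Frames whose contour does not
#' converge are skipped and reported with a reason code. In parallel, each
#' vowel is synthesized per gender at the reference formant frequencies and
#' re-analyzed by LPC; the per-vowel articulatory means (the phantom postures
#' are gender-neutral, so the same means serve both genders) are then
#' correlated with the per-vowel F1 and F2 means.
#'
#' With `tables_only = TRUE`, summaries and correlations are computed
#' directly from the reference tables ([articulatory_table()],
#' [formant_table()]) without any image or audio processing.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, `measurements.csv`,
#'   `summaries.csv`, `formants.csv`, `correlations.csv` and `results.json`
#'   are written there.
#' @return A list of class `pipeline_result` with `measurements`,
#'   `summaries`, `formants`, `correlations` (data frames), `skipped`
#'   (data frame of skipped frames and reasons) and `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$tables_only) {
    tab <- articulatory_table()
    summaries <- reference_summaries()
    long <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
      data.frame(vowel = tab$vowel[i], gender = tab$gender[i],
                 parameter = tab$parameter[i],
                 frame_index = 0:6,
                 value = as.numeric(tab[i, paste0("frame", 1:7)]))))
    sums <- .summaries_df(summaries)
    fmt <- formant_table()
    corr <- correlate_articulatory_acoustic(sums, fmt)
    res <- structure(list(measurements = long, summaries = sums,
                          formants = fmt, correlations = corr,
                          skipped = data.frame(), config = cfg),
                     class = "pipeline_result")
    if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
    return(res)
  }

  arches <- default_archetypes(blur_sigma = cfg$blur_sigma,
                               noise_sd = cfg$noise_sd)
  missing <- setdiff(cfg$vowels, names(arches))
  if (length(missing))
    stop("unknown vowel(s): ", paste(missing, collapse = ", "), call. = FALSE)

  rows <- list(); skipped <- list(); summaries <- list()
  for (v in cfg$vowels) {
    seq_frames <- generate_frame_sequence(
      arches[[v]], n_frames = cfg$n_frames, jitter = cfg$jitter,
      size = cfg$size, seed = .sub_seed(cfg$seed, v),
      resolution = cfg$resolution)
    vals <- list()
    for (fr in seq_frames) {
      plane <- palatal_plane(fr$truth$ans, fr$truth$pns)
      tr <- tryCatch(
        track_frame(fr$frame, plane, fr$truth$jaw_mask,
                    cfg$preprocess, cfg$snake),
        error = function(e) e)
      idx <- fr$frame$frame_index
      if (inherits(tr, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          vowel = v, frame_index = idx, reason = conditionMessage(tr))
        next
      }
      if (!tr$converged) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          vowel = v, frame_index = idx, reason = "contour did not converge")
        next
      }
      m <- measure_parameters(tr$contour, fr$truth$palate_trace,
                              fr$truth$upper_lip, fr$truth$lower_lip,
                              resolution = cfg$resolution, plane = plane,
                              frame_index = idx)
      rows[[length(rows) + 1L]] <- list(vowel = v, m = m)
      vals[[length(vals) + 1L]] <- m
    }
    if (length(vals) == 0)
      stop("every frame of vowel '", v, "' was skipped", call. = FALSE)
    for (p in c("ttcl", "tbcl", "la")) {
      summaries[[length(summaries) + 1L]] <- summarize_frames(
        vapply(vals, function(m) m[[p]], 1), v, "P", toupper(p))
    }
  }

  # acoustics: synthesize each vowel per gender at the reference formants,
  # topped up with neutral higher formants so the spectrum matches a full
  # vocal tract (LPC assumes one)
  fmt_ref <- formant_table()
  fm_rows <- list()
  for (g in c("M", "F")) {
    settings <- do.call(formant_settings_for,
                        c(list(gender = g), cfg$formant_kwargs))
    f0 <- if (g == "M") cfg$f0_male else cfg$f0_female
    for (v in cfg$vowels) {
      ref <- fmt_ref[fmt_ref$vowel == v & fmt_ref$gender == g, ]
      if (nrow(ref) < 2) next
      f12 <- ref$mean_hz[match(c("F1", "F2"), ref$formant)]
      fm <- c(f12, pmax(neutral_upper_formants(g), f12[2] + c(300, 800, 1300)))
      seg <- synthesize_vowel(f0, fm, duration = cfg$audio_duration,
                              seed = .sub_seed(cfg$seed, paste0(g, v)))
      fs <- average_formants(seg, settings, vowel = v, gender = g)
      for (k in seq_len(min(2, length(fs$f_mean))))
        fm_rows[[length(fm_rows) + 1L]] <- data.frame(
          vowel = v, gender = g, formant = paste0("F", k),
          mean_hz = fs$f_mean[k], std_hz = fs$f_std[k])
    }
  }
  formants <- do.call(rbind, fm_rows)

  # correlation: the phantom postures are gender-neutral, so pair the same
  # articulatory means with each gender's formants
  sums <- .summaries_df(summaries)
  if (length(unique(sums$vowel)) >= 3) {
    artic_both <- do.call(rbind, lapply(c("M", "F"), function(g)
      transform(sums, gender = g)))
    corr <- correlate_articulatory_acoustic(artic_both, formants)
  } else corr <- data.frame()  # a correlation needs at least three vowels

  res <- structure(list(
    measurements = .measurements_df(rows), summaries = sums,
    formants = formants, correlations = corr,
    skipped = if (length(skipped)) do.call(rbind, skipped) else data.frame(),
    config = cfg), class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(res$measurements, "measurements.csv")
  wr(res$summaries, "summaries.csv")
  wr(res$formants, "formants.csv")
  wr(res$correlations, "correlations.csv")
  if (nrow(res$skipped)) wr(res$skipped, "skipped.csv")
  json <- list(
    seed = res$config$seed,
    n_measurements = nrow(res$measurements),
    n_skipped = nrow(res$skipped),
    correlations = lapply(seq_len(nrow(res$correlations)), function(i)
      as.list(res$correlations[i, ])))
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "results.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d measurements, %d summaries, %d skipped\n",
              nrow(x$measurements), nrow(x$summaries), nrow(x$skipped)))
  if (nrow(x$correlations)) {
    cat("correlations:\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}
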