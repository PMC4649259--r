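# Study orchestration: configuration, fixture generation, and the full
# simulate -> preprocess -> image classes -> features -> selection/
# clustering -> connectivity flow, with per-stage logging.

#' Default study configuration
#'
#' All stage parameters in one nested list; defaults match the stated
#' analysis conventions (0.1 Hz 8th-order high-pass, 2-s bad-channel
#' windows, 0.5-s / 3-SD ASR, 5-s epochs in 1-s segments, 50 mRMR
#' features, 3 classes, 100 search iterations, 0.3 connectivity
#' threshold). Round-trips losslessly through YAML.
#'
#' @param ... named overrides, e.g. `preprocess = list(corr_threshold = 0.5)`
#'   (merged recursively).
#' @return a `study_config` list.
#' @export
study_config <- function(...) {
  cfg <- list(
    simulate = list(n_subjects = 4, n_pieces = 3, baseline_s = 12,
                    piece_s = 6, fs = 250, seed = 1,
                    class_sequence = c("complex", "moderate", "moderate")),
    preprocess = list(highpass_hz = 0.1, highpass_order = 8,
                      badchan_window_s = 2, corr_threshold = 0.4,
                      frac_channels = 0.8, frac_windows = 0.5,
                      asr = TRUE, asr_window_s = 0.5, asr_k_sd = 3,
                      epoch_s = 5, segment_s = 1),
    images = list(size = 128, n_blocks = 16),
    features = list(domains = "time"),
    selection = list(k = 50),
    clustering = list(n_dim = 2, k_neighbors = 7, lambda = 1,
                      n_hidden = 200, n_iter = 10, method = "gmm",
                      n_classes = 3),
    connectivity = list(enabled = TRUE, p = 5, uc = 1e-3, threshold = 0.3,
                        freq_lo = 1, freq_hi = 50, t_stride_s = 0.01,
                        bands = c("delta", "gamma")),
    seed = 1)
  over <- list(...)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_rec(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  cfg <- merge_rec(cfg, over)
  validate_config(cfg)
  structure(cfg, class = c("study_config", "list"))
}

validate_config <- function(cfg) {
  known_bands <- band_definitions()$name
  bad <- setdiff(cfg$connectivity$bands, known_bands)
  if (length(bad)) stop("unknown band name(s): ", paste(bad, collapse = ", "))
  bad_dom <- setdiff(cfg$features$domains, c("time", "frequency", "wavelet"))
  if (length(bad_dom)) stop("unknown feature domain(s): ",
                            paste(bad_dom, collapse = ", "))
  stopifnot(cfg$simulate$n_subjects >= 1, cfg$simulate$fs > 0,
            cfg$selection$k >= 1, cfg$clustering$n_classes >= 1,
            cfg$connectivity$threshold >= 0)
  invisible(cfg)
}

#' Write / read a study configuration as YAML
#' @param cfg a [study_config()].
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

#' Generate an on-disk synthetic study fixture
#'
#' `tiny`: 4 subjects x 3 pieces at 250 Hz with a 12-s baseline, sized for
#' test suites. `default`: 20 subjects x 8 pieces at 1000 Hz with a 60-s
#' baseline, mirroring a full gel-EEG cohort. Writes BrainVision-style
#' triplets, ground-truth JSON sidecars, stimulus PNGs and a manifest.
#'
#' @param profile `"tiny"` or `"default"`.
#' @param seed integer seed; fixtures are reproducible byte-for-byte.
#' @param dir output directory (created).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the manifest list.
#' @export
make_fixture <- function(profile = c("tiny", "default"), seed = 1,
                         dir = tempfile("fixture_"), overwrite = FALSE) {
  profile <- match.arg(profile)
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("output directory exists and is not empty; use overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- fixture_profile(profile, seed)
  manifest <- list(profile = profile, seed = seed, subjects = list())
  for (i in seq_len(prof$n_subjects)) {
    spec <- fixture_session_spec(prof, i)
    sess <- generate_session(spec)
    stem <- file.path(dir, sprintf("sub%02d", i))
    write_brainvision(sess$recording, stem)
    write_ground_truth(sess$truth, paste0(stem, "_truth.json"))
    manifest$subjects[[i]] <- list(id = spec$subject,
                                   vhdr = paste0(basename(stem), ".vhdr"),
                                   age = spec$age, gender = spec$gender)
  }
  imgdir <- file.path(dir, "images")
  dir.create(imgdir, showWarnings = FALSE)
  for (j in seq_len(prof$n_pieces)) {
    img <- generate_synthetic_images(prof$classes[j], size = 128,
                                     seed = child_seed(seed, 5000 + j))
    write_image(img, file.path(imgdir, sprintf("piece_%d.png", j)))
  }
  wall <- generate_synthetic_images("baseline", size = 128,
                                    seed = child_seed(seed, 5999))
  write_image(wall, file.path(imgdir, "baseline.png"))
  manifest$images <- c(sprintf("images/piece_%d.png", seq_len(prof$n_pieces)),
                       "images/baseline.png")
  manifest$classes <- prof$classes
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(c(manifest, dir = dir))
}

fixture_profile <- function(profile, seed) {
  if (profile == "tiny") {
    list(profile = profile, n_subjects = 4, n_pieces = 3, baseline_s = 12,
         piece_s = 6, fs = 250, seed = seed,
         classes = c("complex", "moderate", "moderate"))
  } else {
    list(profile = profile, n_subjects = 20, n_pieces = 8, baseline_s = 60,
         piece_s = 6, fs = 1000, seed = seed,
         classes = c("complex", "moderate", "moderate", "complex",
                     "moderate", "moderate", "complex", "moderate"))
  }
}

fixture_session_spec <- function(prof, i) {
  ages <- with_seed(child_seed(prof$seed, 3000 + i),
                    sample(20:55, 1))
  session_spec(
    subject = sprintf("sub%02d", i),
    pieces = data.frame(piece = seq_len(prof$n_pieces),
                        class = prof$classes,
                        duration = prof$piece_s),
    baseline_s = prof$baseline_s, fs = prof$fs,
    seed = child_seed(prof$seed, i),
    age = ages, gender = if (i %% 2) "F" else "M")
}

#' Run the full study analogue
#'
#' Executes simulate (in memory) -> preprocess -> image classes ->
#' features -> mRMR + US-ELM clustering -> connectivity contrasts under
#' one configuration, collecting per-stage outputs, parameters and seeds
#' in a run report. Stages fail fast with the stage name in the error.
#'
#' @param cfg a [study_config()].
#' @param progress print per-stage progress messages.
#' @return a `run_report` list: `stages` (timings, parameters), `features`,
#'   `classes`, `ranking`, `search`, `connectivity`, `summary`.
#' @export
run_study <- function(cfg = study_config(), progress = interactive()) {
  validate_config(cfg)
  report <- list(config = cfg, stages = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[[stage]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    if (progress) message(sprintf("[%s] %.1fs", stage,
                                  proc.time()[3] - t0))
    out
  }
  sim <- cfg$simulate
  sessions <- tick("simulate", {
    lapply(seq_len(sim$n_subjects), function(i) {
      prof <- list(n_pieces = sim$n_pieces, baseline_s = sim$baseline_s,
                   piece_s = sim$piece_s, fs = sim$fs, seed = sim$seed,
                   classes = rep_len(sim$class_sequence, sim$n_pieces))
      generate_session(fixture_session_spec(prof, i))
    })
  })
  epoch_sets <- tick("preprocess", {
    lapply(sessions, function(s) {
      pp <- preprocess(s$recording,
                       corr_threshold = cfg$preprocess$corr_threshold,
                       asr = cfg$preprocess$asr,
                       k_sd = cfg$preprocess$asr_k_sd,
                       epoch_len = cfg$preprocess$epoch_s,
                       sub_len = cfg$preprocess$segment_s)
      pp$epochs
    })
  })
  classes <- tick("images", {
    cls <- rep_len(sim$class_sequence, sim$n_pieces)
    imgs <- lapply(seq_len(sim$n_pieces), function(j) {
      image_features(generate_synthetic_images(cls[j], size = cfg$images$size,
                                               seed = child_seed(sim$seed,
                                                                 5000 + j)))
    })
    wall <- image_features(generate_synthetic_images("baseline",
                                                     size = cfg$images$size,
                                                     seed = child_seed(sim$seed, 5999)))
    fm <- do.call(rbind, c(imgs, list(wall)))
    rownames(fm) <- c(sprintf("piece_%d", seq_len(sim$n_pieces)), "baseline")
    cluster_images(fm, baseline = "baseline")
  })
  table <- tick("features", {
    build_feature_table(epoch_sets, domain = cfg$features$domains[1],
                        classes = classes)
  })
  ranking <- tick("selection", {
    mrmr_select(table, k = min(cfg$selection$k,
                               nrow(feature_info(table))))
  })
  search <- tick("clustering", {
    x <- feature_matrix(table)[, ranking$feature, drop = FALSE]
    parameter_search(x, table$class,
                     grid = data.frame(n_dim = cfg$clustering$n_dim,
                                       k_neighbors = cfg$clustering$k_neighbors,
                                       lambda = cfg$clustering$lambda),
                     n_iter = cfg$clustering$n_iter,
                     method = cfg$clustering$method,
                     n_classes = cfg$clustering$n_classes, seed = cfg$seed)
  })
  connectivity <- if (isTRUE(cfg$connectivity$enabled)) {
    tick("connectivity", {
      patterns <- define_patterns(epoch_sets[[1]]$channels)
      per_subject <- lapply(seq_along(epoch_sets), function(i) {
        es <- epoch_sets[[i]]
        pieces <- vapply(es$epochs, `[[`, "", "piece")
        fit_one <- function(ep) {
          m <- fit_mvaar_kalman(ep$data, p = cfg$connectivity$p,
                                uc = cfg$connectivity$uc, fs = es$fs)
          adtf(m, freqs = cfg$connectivity$freq_lo:cfg$connectivity$freq_hi,
               t_stride = max(1, round(cfg$connectivity$t_stride_s * es$fs)))
        }
        base_i <- which(pieces == "baseline")[1]
        view_i <- which(pieces != "baseline")[1]
        if (is.na(base_i) || is.na(view_i)) return(NULL)
        list(baseline = fit_one(es$epochs[[base_i]]),
             viewing = fit_one(es$epochs[[view_i]]))
      })
      per_subject <- Filter(Negate(is.null), per_subject)
      out <- list()
      for (band in cfg$connectivity$bands) {
        for (pn in names(patterns)) {
          vv <- unlist(lapply(per_subject, function(s) {
            pattern_samples(s$viewing, band, patterns[[pn]],
                            cfg$connectivity$threshold)$values
          }))
          bb <- unlist(lapply(per_subject, function(s) {
            pattern_samples(s$baseline, band, patterns[[pn]],
                            cfg$connectivity$threshold)$values
          }))
          out[[paste(band, pn, sep = ":")]] <- compare_conditions(vv, bb)
        }
      }
      list(contrasts = out, patterns = patterns,
           n_subjects = length(per_subject))
    })
  } else NULL
  report$classes <- classes
  report$feature_table <- table
  report$ranking <- ranking
  report$search <- search
  report$connectivity <- connectivity
  report$summary <- list(
    n_subjects = sim$n_subjects,
    n_segments = nrow(table),
    n_features = nrow(feature_info(table)),
    best_mean_rand = search$best$mean_rand,
    best_mean_agreement = search$best$mean_agreement)
  class(report) <- "run_report"
  report
}

#' End-to-end unsupervised clustering benchmark
#'
#' Runs the canonical study analogue in memory: generate a cohort of
#' synthetic sessions, preprocess, assign image complexity classes by
#' hierarchical clustering of stimulus-image features, build the
#' time-domain feature table, rank features with mRMR, and repeat the
#' US-ELM embedding + clustering for `n_iter` random hidden layers,
#' scoring each iteration against the class labels with the Rand index.
#'
#' @param profile `"default"` (20 subjects x 8 pieces at 1000 Hz) or
#'   `"tiny"` (4 subjects x 3 pieces at 250 Hz).
#' @param n_iter embedding/clustering iterations.
#' @param k number of mRMR-ranked features kept.
#' @param method clustering method (`"gmm"` or `"kmeans"`).
#' @param seed integer seed.
#' @param progress print per-subject progress.
#' @return list with `mean_rand`, `mean_agreement`, the full `search`
#'   result, the feature `ranking` and the image-derived `classes`.
#' @export
clustering_benchmark <- function(profile = c("default", "tiny"),
                                 n_iter = 100, k = 50, method = "gmm",
                                 seed = 1, progress = FALSE) {
  profile <- match.arg(profile)
  prof <- fixture_profile(profile, seed)
  esets <- lapply(seq_len(prof$n_subjects), function(i) {
    if (progress) message("subject ", i, "/", prof$n_subjects)
    sess <- generate_session(fixture_session_spec(prof, i))
    preprocess(sess$recording)$epochs
  })
  imgs <- do.call(rbind, lapply(seq_len(prof$n_pieces), function(j) {
    image_features(generate_synthetic_images(prof$classes[j], size = 128,
                                             seed = child_seed(seed, 5000 + j)))
  }))
  wall <- image_features(generate_synthetic_images("baseline", size = 128,
                                                   seed = child_seed(seed, 5999)))
  fm <- rbind(imgs, wall)
  rownames(fm) <- c(sprintf("piece_%d", seq_len(prof$n_pieces)), "baseline")
  classes <- cluster_images(fm, baseline = "baseline")
  table <- build_feature_table(esets, domain = "time", classes = classes)
  ranking <- mrmr_select(table, k = min(k, nrow(feature_info(table))))
  x <- feature_matrix(table)[, ranking$feature, drop = FALSE]
  search <- parameter_search(x, table$class, n_iter = n_iter,
                             method = method, seed = seed)
  list(mean_rand = search$best$mean_rand,
       mean_agreement = search$best$mean_agreement,
       search = search, ranking = ranking, classes = classes,
       n_observations = nrow(table))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  subjects:", x$summary$n_subjects,
      " segments:", x$summary$n_segments,
      " features:", x$summary$n_features, "\n")
  cat(sprintf("  clustering: mean Rand %.3f, mean agreement %.3f\n",
              x$summary$best_mean_rand, x$summary$best_mean_agreement))
  if (!is.null(x$connectivity)) {
    sig <- vapply(x$connectivity$contrasts, function(ct) {
      isTRUE(ct$comparable) && ct$p_greater < 0.05
    }, logical(1))
    cat(sprintf("  connectivity contrasts: %d/%d viewing > baseline at p < 0.05\n",
                sum(sig), length(sig)))
  }
  for (s in names(x$stages)) {
    cat(sprintf("  [%s] %.1fs\n", s, x$stages[[s]]$seconds))
  }
  invisible(x)
}
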