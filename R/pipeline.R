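# Orchestration of the full analysis on synthetic multi-subject data:
# simulate -> preprocess -> power/SSD -> coupling -> delay -> statistics ->
# connectomics, with per-stage artifacts on disk and a hash manifest.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    n_subjects = 6L,
    conditions = c("off", "levodopa"),
    sim = list(),
    levodopa_gain = 0.5,
    epoch_duration = 2,
    resample_rate = 500,
    delay_rate = 1000,
    z_thresh = 4,
    multitaper_bandwidth = 5,
    n_segments_coupling = 200L,
    n_segments_delay = 400L,
    var_order = 60L,
    n_perm = 100000L,
    stat_band = c(3, 50),
    bands = list(low_beta = c(12, 20), high_beta = c(20, 30)),
    tde_band = c(3, 100),
    stages = c(
      "simulate", "preprocess", "power", "coupling", "tde",
      "stats", "connectome"
    )
  )
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected; the resolved configuration is written next
#' to the outputs of every run. Defaults follow the reference analysis
#' (2 s epochs at 500 Hz, 5 Hz multitaper bandwidth, 200 coupling and 400
#' delay bootstrap segments, VAR order 60, 100000 permutations); scaled
#' runs override them explicitly.
#'
#' @param ... Overrides of the default fields.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg <- utils::modifyList(defaults, overrides)
  bad_stages <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad_stages)) {
    stop("unknown stage(s): ", paste(bad_stages, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

subject_ids <- function(n) sprintf("%02d", seq_len(n))

#' Run the full synthetic analysis pipeline
#'
#' Simulates a multi-subject cohort in two therapy conditions (the ON
#' levodopa condition attenuates the cortex -> STN coupling gain), then
#' runs preprocessing, spectral power and SSD, undirected and directed
#' coupling, bispectral delay estimation, paired permutation statistics,
#' and the connectomic mixed-model stage, writing per-stage TSV/JSON
#' artifacts and a manifest of MD5 hashes. Deterministic given the
#' configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_json(unclass(config), file.path(out_dir, "config.json"))
  subjects <- subject_ids(config$n_subjects)
  results <- list()

  ## ---- simulate ----------------------------------------------------------
  recordings <- list()
  ground_truth <- list()
  if ("simulate" %in% config$stages) {
    sim_dir <- file.path(out_dir, "simulate")
    dir.create(sim_dir, showWarnings = FALSE)
    for (s in subjects) {
      for (cond in config$conditions) {
        sc_args <- config$sim
        sc_args$seed <- derive_seed(config$seed, paste("sim", s, cond))
        if (cond == "levodopa") {
          base_gain <- sc_args$coupling_gain %||% 1
          sc_args$coupling_gain <- base_gain * config$levodopa_gain
        }
        sc <- do.call(sim_config, sc_args)
        src <- simulate_sources(sc)
        out <- couple_and_mix(src, sc)
        rec <- out$recording
        rec$subject_id <- s
        rec$condition <- cond
        key <- paste(s, cond, sep = ".")
        recordings[[key]] <- rec
        ground_truth[[key]] <- out$ground_truth
        write_recording(rec, sim_dir)
        write_json(
          list(
            true_delay = out$ground_truth$true_delay,
            true_direction = out$ground_truth$true_direction,
            source_band = out$ground_truth$source_band,
            coupling_gain = sc$coupling_gain
          ),
          file.path(sim_dir, sprintf("sub-%s_%s_truth.json", s, cond))
        )
      }
    }
    results$ground_truth <- ground_truth
  }

  ## ---- preprocess --------------------------------------------------------
  prep <- list()
  if ("preprocess" %in% config$stages) {
    report <- list()
    for (key in names(recordings)) {
      rec <- recordings[[key]]
      rec <- notch_filter(rec, 50)
      rec <- bandpass_filter(rec, 3, 150)
      bip <- bipolar_reference(rec)
      ep_uni <- reject_artifact_epochs(
        make_epochs(rec, config$epoch_duration), config$z_thresh
      )
      ep_bip <- reject_artifact_epochs(
        make_epochs(bip, config$epoch_duration), config$z_thresh
      )
      prep[[key]] <- list(
        uni500 = resample_epochs(ep_uni, config$resample_rate),
        bip500 = resample_epochs(ep_bip, config$resample_rate),
        bip1000 = resample_epochs(ep_bip, config$delay_rate)
      )
      report[[key]] <- list(
        rejected_unipolar = ep_uni$rejection_log$n_rejected,
        rejected_bipolar = ep_bip$rejection_log$n_rejected,
        n_epochs = dim(ep_uni$data)[1]
      )
    }
    dir.create(file.path(out_dir, "preprocess"), showWarnings = FALSE)
    write_json(report, file.path(out_dir, "preprocess", "report.json"))
    results$preprocess <- report
  }

  ## ---- power -------------------------------------------------------------
  if ("power" %in% config$stages) {
    pow_dir <- file.path(out_dir, "power")
    dir.create(pow_dir, showWarnings = FALSE)
    pow_rows <- list()
    ssd_rows <- list()
    for (key in names(prep)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      ep <- prep[[key]]$bip500
      psd <- multitaper_psd(ep, config$multitaper_bandwidth)
      psd_n <- normalize_percent_total(psd)
      for (band_name in names(config$bands)) {
        ba <- band_average(psd_n, config$bands[[band_name]])
        pow_rows[[length(pow_rows) + 1L]] <- data.frame(
          subject = parts[1], condition = parts[2],
          channel = names(ba), band = band_name, value = unname(ba)
        )
      }
      for (site in c("cortex", "stn")) {
        rr <- reduce_rank(ep, site, "bipolar")
        rownames(rr$projection) <- rr$channel_names
        for (band_name in names(config$bands)) {
          sf <- ssd_fit(rr$epochs, config$bands[[band_name]],
            projection = rr$projection,
            channel_names = rr$channel_names
          )
          ssd_rows[[length(ssd_rows) + 1L]] <- data.frame(
            subject = parts[1], condition = parts[2], site = site,
            band = band_name, channel = sf$channel_names,
            pattern_z = sf$patterns_z[, 1],
            top_eigenvalue = sf$snr_eigenvalues[1]
          )
        }
      }
    }
    write_tsv(do.call(rbind, pow_rows), file.path(pow_dir, "band_power.tsv"))
    write_tsv(do.call(rbind, ssd_rows), file.path(pow_dir, "ssd_patterns.tsv"))
    results$power <- do.call(rbind, pow_rows)
    results$ssd <- do.call(rbind, ssd_rows)
  }

  ## ---- coupling ----------------------------------------------------------
  coupling_store <- list()
  if ("coupling" %in% config$stages) {
    cpl_dir <- file.path(out_dir, "coupling")
    dir.create(cpl_dir, showWarnings = FALSE)
    cpl_rows <- list()
    pat_rows <- list()
    for (key in names(prep)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      ep <- prep[[key]]$uni500
      segs <- bootstrap_segments(ep,
        n_segments = config$n_segments_coupling,
        seed = derive_seed(config$seed, paste("seg", key))
      )
      # remap absolute epoch indices to kept-epoch positions for the tensor
      seg_idx <- lapply(segs$segments, function(ix) {
        match(ix, which(ep$kept_mask))
      })

      rr_c <- reduce_rank(ep, "cortex", "unipolar")
      rr_s <- reduce_rank(ep, "stn", "unipolar")
      red <- combine_epochs(rr_c$epochs, rr_s$epochs)
      seed_red <- seq_len(dim(rr_c$epochs$data)[2])
      targ_red <- dim(rr_c$epochs$data)[2] + seq_len(dim(rr_s$epochs$data)[2])

      tens_uni <- csd_epoch_tensor(ep, config$multitaper_bandwidth)
      tens_red <- csd_epoch_tensor(red, config$multitaper_bandwidth)
      seed_uni <- which(ep$channel_info$site == "cortex")
      targ_uni <- which(ep$channel_info$site == "stn")

      ic_list <- list()
      mic_list <- list()
      gc_list <- list()
      for (si in seq_along(seg_idx)) {
        csd_u <- csd_from_tensor(tens_uni, seg_idx[[si]])
        csd_r <- csd_from_tensor(tens_red, seg_idx[[si]])
        ic_list[[si]] <- imcoh_grand_average(csd_u, seed_uni, targ_uni)
        mic_list[[si]] <- mic(csd_r, seed_red, targ_red,
          seed_projection = rr_c$projection,
          target_projection = rr_s$projection
        )
        gc_list[[si]] <- trgc(csd_r, seed_red, targ_red,
          order = config$var_order, freq_range = config$stat_band
        )
      }
      ic <- average_segments(ic_list)
      mc <- average_segments(mic_list)
      gc <- average_segments(gc_list)
      coupling_store[[key]] <- list(imcoh = ic, mic = mc, trgc = gc)

      for (sp in list(ic, mc, gc)) {
        cpl_rows[[length(cpl_rows) + 1L]] <- data.frame(
          subject = parts[1], condition = parts[2], method = sp$method,
          frequency = sp$freqs, value = sp$values
        )
      }
      ci <- ep$channel_info
      for (band_name in names(config$bands)) {
        b <- config$bands[[band_name]]
        sel <- mc$freqs >= b[1] & mc$freqs <= b[2]
        pat_rows[[length(pat_rows) + 1L]] <- data.frame(
          subject = parts[1], condition = parts[2], band = band_name,
          channel = c(
            ci$name[seed_uni], ci$name[targ_uni]
          ),
          site = c(ci$site[seed_uni], ci$site[targ_uni]),
          mni_x = c(ci$mni_x[seed_uni], ci$mni_x[targ_uni]),
          mni_y = c(ci$mni_y[seed_uni], ci$mni_y[targ_uni]),
          mni_z = c(ci$mni_z[seed_uni], ci$mni_z[targ_uni]),
          pattern_z = c(
            rowMeans(mc$seed_patterns_z[, sel, drop = FALSE]),
            rowMeans(mc$target_patterns_z[, sel, drop = FALSE])
          )
        )
      }
    }
    write_tsv(do.call(rbind, cpl_rows), file.path(cpl_dir, "coupling_spectra.tsv"))
    write_tsv(do.call(rbind, pat_rows), file.path(cpl_dir, "mic_patterns.tsv"))
    results$coupling <- coupling_store
    results$mic_patterns <- do.call(rbind, pat_rows)
  }

  ## ---- tde ---------------------------------------------------------------
  if ("tde" %in% config$stages) {
    tde_dir <- file.path(out_dir, "tde")
    dir.create(tde_dir, showWarnings = FALSE)
    tde_rows <- list()
    bin_rows <- list()
    for (key in names(prep)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      ep <- prep[[key]]$bip1000
      segs <- bootstrap_segments(ep,
        n_segments = config$n_segments_delay,
        seed = derive_seed(config$seed, paste("tdeseg", key))
      )
      seg_idx <- lapply(segs$segments, function(ix) match(ix, which(ep$kept_mask)))
      segs$segments <- seg_idx
      # analyse the strongest (largest-variance) channel of each site
      ch_var <- apply(kept_epoch_data(ep), 2, stats::var)
      cortex_set <- which(ep$channel_info$site == "cortex" &
        ep$channel_info$region == "motor")
      if (length(cortex_set) == 0) cortex_set <- which(ep$channel_info$site == "cortex")
      seed_ch <- cortex_set[which.max(ch_var[cortex_set])]
      stn_set <- which(ep$channel_info$site == "stn")
      targ_ch <- stn_set[which.max(ch_var[stn_set])]
      n_pts <- 2L * dim(ep$data)[3] + 1L
      co_seed <- fourier_coefficients(ep, seed_ch,
        n_points = n_pts, expected_rate = config$delay_rate
      )
      co_targ <- fourier_coefficients(ep, targ_ch,
        n_points = n_pts, expected_rate = config$delay_rate
      )
      de <- bootstrap_delay(co_seed, co_targ, segs, band = config$tde_band)
      pk <- peak_binning(de)
      tde_rows[[length(tde_rows) + 1L]] <- data.frame(
        subject = parts[1], condition = parts[2],
        seed = ep$channel_info$name[seed_ch],
        target = ep$channel_info$name[targ_ch],
        tau = de$tau, ci_lo = de$ci80[1], ci_hi = de$ci80[2],
        valid = de$valid
      )
      if (pk$defined) {
        bin_rows[[length(bin_rows) + 1L]] <- data.frame(
          subject = parts[1], condition = parts[2],
          bin = names(pk$bin_percentages),
          percentage = unname(pk$bin_percentages)
        )
      }
    }
    write_tsv(do.call(rbind, tde_rows), file.path(tde_dir, "delays.tsv"))
    if (length(bin_rows)) {
      write_tsv(do.call(rbind, bin_rows), file.path(tde_dir, "peak_bins.tsv"))
    }
    results$tde <- do.call(rbind, tde_rows)
  }

  ## ---- stats -------------------------------------------------------------
  if ("stats" %in% config$stages && length(config$conditions) >= 2 &&
    "coupling" %in% config$stages) {
    st_dir <- file.path(out_dir, "stats")
    dir.create(st_dir, showWarnings = FALSE)
    rows <- list()
    cond_a <- config$conditions[1]
    cond_b <- config$conditions[2]
    for (method in c("imcoh", "mic")) {
      spectra_a <- t(vapply(
        subjects,
        function(s) coupling_store[[paste(s, cond_a, sep = ".")]][[method]]$values,
        numeric(length(coupling_store[[1]][[method]]$freqs))
      ))
      spectra_b <- t(vapply(
        subjects,
        function(s) coupling_store[[paste(s, cond_b, sep = ".")]][[method]]$values,
        numeric(length(coupling_store[[1]][[method]]$freqs))
      ))
      freqs <- coupling_store[[1]][[method]]$freqs
      for (band_name in names(config$bands)) {
        b <- config$bands[[band_name]]
        sel <- freqs >= b[1] & freqs <= b[2]
        pr <- paired_permutation(
          rowMeans(spectra_a[, sel, drop = FALSE]),
          rowMeans(spectra_b[, sel, drop = FALSE]),
          n_perm = config$n_perm,
          seed = derive_seed(config$seed, paste("stat", method, band_name))
        )
        rows[[length(rows) + 1L]] <- data.frame(
          measure = method, contrast = paste(cond_a, "vs", cond_b),
          band = band_name, observed_t = pr$observed_stat,
          p = pr$p_value, corrected = FALSE
        )
      }
      sel <- freqs >= config$stat_band[1] & freqs <= config$stat_band[2]
      cl <- cluster_permutation(
        spectra_a[, sel, drop = FALSE], spectra_b[, sel, drop = FALSE],
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, paste("clu", method))
      )
      for (clu in cl$clusters) {
        rows[[length(rows) + 1L]] <- data.frame(
          measure = method, contrast = paste(cond_a, "vs", cond_b),
          band = sprintf(
            "%g-%g Hz", freqs[sel][clu$from],
            freqs[sel][clu$to]
          ),
          observed_t = clu$mass, p = clu$p, corrected = TRUE
        )
      }
    }
    st <- do.call(rbind, rows)
    write_tsv(st, file.path(st_dir, "contrasts.tsv"))
    results$stats <- st
  }

  ## ---- connectome --------------------------------------------------------
  if ("connectome" %in% config$stages && "coupling" %in% config$stages) {
    cn_dir <- file.path(out_dir, "connectome")
    dir.create(cn_dir, showWarnings = FALSE)
    pat <- results$mic_patterns
    pat <- pat[pat$band == "high_beta", ]
    tab_rows <- list()
    for (s in subjects) {
      for (cond in config$conditions) {
        p_sc <- pat[pat$subject == s & pat$condition == cond, ]
        ecog <- p_sc[p_sc$site == "cortex", ]
        stn <- p_sc[p_sc$site == "stn", ]
        # pair-exclusive streamlines need contacts separated by more than
        # twice the inclusion radius; thin each set greedily
        ecog <- ecog[separated_subset(ecog[, c("mni_x", "mni_y", "mni_z")], 2 * 5 + 1), ]
        stn <- stn[separated_subset(stn[, c("mni_x", "mni_y", "mni_z")], 2 * 3 + 1), ]
        geom <- list(
          ecog = as.matrix(ecog[, c("mni_x", "mni_y", "mni_z")]),
          stn = as.matrix(stn[, c("mni_x", "mni_y", "mni_z")])
        )
        pair_pattern <- outer(ecog$pattern_z, stn$pattern_z, `+`) / 2
        noise_seed <- derive_seed(config$seed, paste("fibers", s, cond))
        counts <- with_seed(noise_seed, {
          matrix(
            pmax(0L, as.integer(round(
              3 + 2 * pair_pattern +
                stats::rnorm(length(pair_pattern), sd = 0.5)
            ))),
            nrow(pair_pattern), ncol(pair_pattern)
          )
        })
        atlas <- simulate_fiber_atlas(geom, counts, seed = noise_seed)
        write_streamlines_tsv(
          atlas,
          file.path(cn_dir, sprintf("sub-%s_%s_streamlines.tsv", s, cond))
        )
        for (i in seq_len(nrow(ecog))) {
          for (j in seq_len(nrow(stn))) {
            fc <- count_connecting_fibers(
              atlas, geom$ecog[i, ], geom$stn[j, ]
            )
            tab_rows[[length(tab_rows) + 1L]] <- data.frame(
              subject = s,
              medication = as.integer(cond == "levodopa"),
              pattern = pair_pattern[i, j], response = fc
            )
          }
        }
      }
    }
    tab <- do.call(rbind, tab_rows)
    write_tsv(tab, file.path(cn_dir, "fiber_table.tsv"))
    fit <- lme_fit(tab)
    write_json(
      list(
        fixed_effects = fit$fixed_effects,
        conditional_r2 = fit$conditional_r2, bic = fit$bic,
        fit_quality_r = fit$fit_quality_r, singular = fit$singular
      ),
      file.path(cn_dir, "lme_fit.json")
    )
    results$connectome <- fit
  }

  ## ---- manifest ----------------------------------------------------------
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest.json$", files)]
  hashes <- tools::md5sum(files)
  manifest <- list(
    seed = config$seed,
    files = data.frame(
      file = sub(paste0("^", gsub("([.|()\\^{}+$*?])", "\\\\\\1", out_dir), "/?"), "", files),
      md5 = unname(hashes)
    )
  )
  write_json(manifest, file.path(out_dir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

# Greedily keep rows whose pairwise Euclidean distance to every kept row
# is at least min_dist.
separated_subset <- function(xyz, min_dist) {
  xyz <- as.matrix(xyz)
  keep <- 1L
  for (i in seq_len(nrow(xyz))[-1]) {
    d <- sqrt(rowSums((xyz[keep, , drop = FALSE] -
      matrix(xyz[i, ], length(keep), 3, byrow = TRUE))^2))
    if (all(d >= min_dist)) keep <- c(keep, i)
  }
  keep
}

# Concatenate two epochs objects along the channel dimension (same epoch
# grid and rate).
combine_epochs <- function(a, b) {
  stopifnot(
    all(dim(a$data)[c(1, 3)] == dim(b$data)[c(1, 3)]),
    a$sampling_rate == b$sampling_rate
  )
  d <- dim(a$data)
  out <- array(0, dim = c(d[1], d[2] + dim(b$data)[2], d[3]))
  out[, seq_len(d[2]), ] <- a$data
  out[, d[2] + seq_len(dim(b$data)[2]), ] <- b$data
  new_epochs(out, a$sampling_rate, rbind(a$channel_info, b$channel_info),
    kept_mask = a$kept_mask & b$kept_mask,
    condition = a$condition, subject_id = a$subject_id
  )
}
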