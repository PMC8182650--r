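#' Assemble and validate a pipeline configuration
#'
#' A nested list mirroring the stage parameters: `simulate` holds the
#' [sim_config()] arguments plus `n_replicates`, `format` and `pitch`;
#' `cluster`, `score` and `barseq` hold their stages' tuning knobs. All
#' randomness flows from the single `seed` via named per-stage substreams
#' ([stage_seed()]). Unknown keys anywhere are rejected by name, so typos
#' in config files fail loudly.
#'
#' @param seed global seed.
#' @param out_dir output directory for all stage artifacts.
#' @param simulate,cluster,score,barseq named lists of stage options.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "pipeline_out",
                            simulate = list(), cluster = list(),
                            score = list(), barseq = list()) {
    allowed <- list(
        simulate = c(names(formals(sim_config)), "n_replicates", "format",
                     "pitch"),
        cluster = c("k", "low_threshold", "drop_threshold"),
        score = c("trim_top", "trim_bottom", "toxicity_threshold",
                  "sdl_cutoff", "dependence_low", "dependence_high"),
        barseq = c("max_mismatch", "flank_mismatch", "flank_offset",
                   "floor_quantile", "k", "read_length")
    )
    for (st in names(allowed)) {
        given <- get(st)
        unknown <- setdiff(names(given), allowed[[st]])
        if (length(unknown))
            stop("unknown ", st, " config key(s): ",
                 paste(unknown, collapse = ", "))
    }
    simulate$seed <- NULL
    structure(list(seed = as.integer(seed), out_dir = out_dir,
                   simulate = simulate, cluster = cluster, score = score,
                   barseq = barseq),
              class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file's top-level keys must be arguments of [pipeline_config()];
#' unknown keys (at either level) are rejected with the offending key
#' named. Values in `overrides` take precedence over file values.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param overrides named list merged over the file contents.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        yaml::read_yaml(path)
    } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = TRUE)
    } else stop("config must be YAML or JSON: ", path)
    unknown <- setdiff(names(raw), names(formals(pipeline_config)))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in names(overrides)) raw[[k]] <- overrides[[k]]
    do.call(pipeline_config, raw)
}

#' Run the phenotyping pipeline end to end
#'
#' Executes the requested stages in order — `simulate` (strain panel,
#' growth table, plate images, BAR-seq FASTQ), `quantify` (grid detection,
#' colony measurement, normalization), `growth` (curves and AUGC
#' matrices), `cluster` (dose-response behavior clustering), `score` (Aux,
#' toxicity, dependence and SDL tables) and `barseq` (counting, fitness,
#' fitness clustering) — writing TSV artifacts under `config$out_dir` and
#' a JSON run manifest with the md5 checksum of every output. Stages read
#' the artifacts of earlier stages, so a later stage can be re-run against
#' an existing directory.
#'
#' @param config a [pipeline_config()].
#' @param stages ordered subset of the six stage names.
#' @return invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "quantify", "growth",
                                    "cluster", "score", "barseq")) {
    stopifnot(inherits(config, "pipeline_config"))
    stages <- match.arg(stages, several.ok = TRUE)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    scfg <- do.call(sim_config, c(config$simulate[setdiff(names(config$simulate),
                                      c("n_replicates", "format", "pitch"))],
                                  list(seed = config$seed)))
    n_rep <- config$simulate$n_replicates %||% 4L
    format <- config$simulate$format %||% 384L
    pitch <- config$simulate$pitch %||% 20L
    out <- function(...) file.path(config$out_dir, ...)
    timing <- c()

    for (st in stages) {
        t0 <- proc.time()[["elapsed"]]
        message("[", st, "] started")
        switch(st,
        simulate = {
            panel <- make_strain_panel(scfg)
            write_tsv(as.data.frame(panel), out("panel.tsv"),
                      meta = list(seed = scfg$seed))
            growth <- simulate_growth(panel, scfg, n_replicates = n_rep)
            write_tsv(as.data.frame(growth), out("growth.tsv"))
            render_plate_series(growth, scfg, out("images"),
                                format = format, pitch = pitch)
            pool <- simulate_pool(panel, scfg)
            run <- simulate_barseq_run(panel, pool, scfg, out("fastq"),
                                       read_length = config$barseq$read_length %||% 60L)
            write_tsv(run$samples, out("sample_sheet.tsv"))
            write_tsv(cbind(strain_id = rownames(run$true_counts),
                            as.data.frame(run$true_counts)),
                      out("true_counts.tsv"))
        },
        quantify = {
            layout <- plate_layout(format)
            map <- read_tsv(out(file.path("images", "plate_map.tsv")))
            truth <- read_tsv(out(file.path("images", "render_truth.tsv")))
            imgs <- unique(truth[, c("plate_id", "medium", "dose_nM", "time_h")])
            tabs <- vector("list", nrow(imgs))
            # detect each plate's grid on its final (fullest) image and
            # reuse it for the earlier, sparser timepoints
            grids <- list()
            for (pid in unique(imgs$plate_id)) {
                tlast <- max(imgs$time_h[imgs$plate_id == pid])
                f <- out(file.path("images",
                                   sprintf("%s_t%05.1f.tif", pid, tlast)))
                grids[[pid]] <- detect_grid(read_plate_image(f),
                                            layout$n_rows, layout$n_cols)
            }
            for (i in seq_len(nrow(imgs))) {
                f <- out(file.path("images",
                                   sprintf("%s_t%05.1f.tif", imgs$plate_id[i],
                                           imgs$time_h[i])))
                tabs[[i]] <- quantify_plate(f, layout$n_rows, layout$n_cols,
                                            plate_id = imgs$plate_id[i],
                                            medium = imgs$medium[i],
                                            dose_nM = imgs$dose_nM[i],
                                            time_h = imgs$time_h[i],
                                            grid = grids[[imgs$plate_id[i]]])
            }
            sizes <- do.call(rbind, tabs)
            sizes$array <- as.integer(sub(".*_a(\\d+)$", "\\1",
                                          sizes$plate_id))
            sizes <- merge(sizes, map, by = c("array", "row", "col"),
                           all.x = TRUE)
            sizes <- normalize_sizes(sizes)
            sizes <- sizes[order(sizes$plate_id, sizes$time_h, sizes$row,
                                 sizes$col),
                           c("plate_id", "medium", "dose_nM", "time_h", "row",
                             "col", "strain_id", "replicate", "raw_size",
                             "normalized_size", "edge_flag", "excluded_flag",
                             "low_quality_flag")]
            write_tsv(sizes, out("sizes.tsv"))
        },
        growth = {
            sizes <- read_tsv(out("sizes.tsv"))
            keep <- !sizes$excluded_flag | sizes$strain_id == "WT_SPIKE"
            sizes <- sizes[keep & !is.na(sizes$normalized_size), ]
            curves_all <- list()
            for (med in unique(sizes$medium)) {
                cur <- build_curves(sizes[sizes$medium == med, ])
                curves_all[[med]] <- cur
                am <- compute_augc_matrix(cur)
                write_tsv(cbind(strain_id = rownames(am),
                                as.data.frame(unclass(am), check.names = FALSE)),
                          out(sprintf("augc_%s.tsv", med)),
                          meta = list(reference = attr(am, "reference_strain"),
                                      window = attr(am, "window")))
            }
            write_tsv(do.call(rbind, curves_all), out("curves.tsv"))
        },
        cluster = {
            med <- sub("^augc_(.*)\\.tsv$", "\\1",
                       basename(list.files(config$out_dir,
                                           pattern = "^augc_.*\\.tsv$")))[1L]
            am <- read_augc_tsv(out(sprintf("augc_%s.tsv", med)))
            k <- config$cluster$k %||% 5L
            prof <- cluster_profiles(am, k = min(k, nrow(am)),
                label_args = config$cluster[intersect(names(config$cluster),
                                 c("low_threshold", "drop_threshold"))])
            write_tsv(as.data.frame(prof), out("clusters.tsv"),
                      meta = list(k = k, metric = "chebyshev",
                                  linkage = "average"))
        },
        score = {
            run_score_stage(config, out)
        },
        barseq = {
            panel <- read_tsv(out("panel.tsv"))
            sheet <- read_tsv(out("sample_sheet.tsv"))
            idx <- build_index(panel,
                               max_mismatch = config$barseq$max_mismatch %||% 2L)
            counts <- count_reads(sheet, idx,
                flank_mismatch = config$barseq$flank_mismatch %||% 1L,
                flank_offset = config$barseq$flank_offset %||% 2L)
            write_tsv(cbind(strain_id = rownames(counts),
                            as.data.frame(unclass(counts), check.names = FALSE)),
                      out("counts.tsv"),
                      meta = list(assigned = attr(counts, "totals")$assigned,
                                  total = attr(counts, "totals")$total))
            fit <- fitness_log2fc(counts,
                floor_quantile = config$barseq$floor_quantile %||% 0.05)
            write_tsv(cbind(strain_id = rownames(fit),
                            as.data.frame(unclass(fit), check.names = FALSE)),
                      out("fitness.tsv"),
                      meta = list(floor = attr(fit, "floor")))
            fc <- cluster_fitness(fit, k = config$barseq$k %||% 3L)
            write_tsv(as.data.frame(fc), out("fitness_clusters.tsv"))
        })
        timing[st] <- round(proc.time()[["elapsed"]] - t0, 2)
        message("[", st, "] done in ", timing[st], " s")
    }

    cfg_file <- out("config_echo.json")
    jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                         digits = NA, null = "null")
    files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                     "manifest.json")
    sums <- tools::md5sum(file.path(config$out_dir, files))
    names(sums) <- files
    manifest <- list(tool = "estrascreen",
                     version = as.character(utils::packageVersion("estrascreen")),
                     seed = config$seed,
                     config_md5 = unname(tools::md5sum(cfg_file)),
                     stages = stages, timing_s = as.list(timing),
                     checksums = as.list(sums),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(manifest)
}

read_augc_tsv <- function(path) {
    df <- read_tsv(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$strain_id
    m
}

# per-strain score tables from the simulate/quantify/growth artifacts
run_score_stage <- function(config, out) {
    growth <- read_tsv(out("growth.tsv"))
    tmax <- max(growth$time_h)
    final <- growth[growth$time_h == tmax, ]
    agg <- stats::aggregate(area ~ strain_id + medium + dose_nM, data = final,
                            FUN = mean)

    pull <- function(med, dose) {
        v <- agg$area[agg$medium == med & agg$dose_nM == dose]
        ids <- agg$strain_id[agg$medium == med & agg$dose_nM == dose]
        setNames(v, ids)
    }
    have <- function(med, dose)
        any(agg$medium == med & agg$dose_nM == dose)

    if (all(c(have("YNB", 0), have("YNB", 1), have("SC", 0), have("SC", 1)))) {
        ids <- sort(unique(agg$strain_id))
        aux <- aux_scores(data.frame(strain_id = ids,
                                     G_M0 = pull("YNB", 0)[ids],
                                     G_M1 = pull("YNB", 1)[ids],
                                     G_R0 = pull("SC", 0)[ids],
                                     G_R1 = pull("SC", 1)[ids]))
        write_tsv(aux, out("aux_scores.tsv"))
    }
    med <- if (have("SC", 100)) "SC" else unique(agg$medium)[1L]
    if (have(med, 0) && have(med, 100)) {
        ids <- sort(unique(agg$strain_id))
        x <- pull(med, 0)[ids]; y <- pull(med, 100)[ids]
        if (length(ids) >= 50L) {
            tox <- toxicity_call(x, y, strain_id = ids,
                trim_top = config$score$trim_top %||% 0.02,
                trim_bottom = config$score$trim_bottom %||% 0.04,
                threshold = config$score$toxicity_threshold %||% 2000)
            write_tsv(as.data.frame(tox), out("toxicity.tsv"),
                      meta = list(threshold = attr(tox, "threshold"),
                                  m = attr(tox, "m"), b = attr(tox, "b")))
        }
    }
    if (have(med, 0) && have(med, 1000)) {
        sizes <- read_tsv(out("sizes.tsv"))
        sizes <- sizes[!sizes$edge_flag & sizes$time_h == max(sizes$time_h) &
                       sizes$medium == med & sizes$replicate %in% 1:2, ]
        s0 <- sizes[sizes$dose_nM == 0, ]
        s1k <- sizes[sizes$dose_nM == 1000, ]
        ids <- sort(intersect(s0$strain_id, s1k$strain_id))
        mk <- function(d, r) {
            v <- d$normalized_size[d$replicate == r]
            setNames(v, d$strain_id[d$replicate == r])[ids]
        }
        sdl <- sdl_call(cbind(mk(s1k, 1), mk(s1k, 2)),
                        cbind(mk(s0, 1), mk(s0, 2)), strain_id = ids,
                        cutoff = config$score$sdl_cutoff %||% -0.08)
        write_tsv(sdl, out("sdl.tsv"))
    }
    files <- list.files(dirname(out("x")), pattern = "^augc_.*\\.tsv$")
    if (length(files)) {
        am <- read_augc_tsv(out(files[1L]))
        doses <- as.numeric(colnames(am))
        dep <- t(vapply(rownames(am), function(s) {
            r <- classify_dependence(am[s, ], doses,
                low_cutoff = config$score$dependence_low %||% 0.25,
                high_cutoff = config$score$dependence_high %||% 0.75)
            c(class = r$class, ratio = as.character(r$ratio))
        }, character(2)))
        write_tsv(data.frame(strain_id = rownames(am),
                             class = dep[, "class"],
                             ratio = as.numeric(dep[, "ratio"]),
                             stringsAsFactors = FALSE),
                  out("dependence.tsv"))
    }
    invisible(NULL)
}
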