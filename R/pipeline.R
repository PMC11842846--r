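#' Configuration for an end-to-end pipeline run
#'
#' @param mode Input mode: `"synthetic"` (generate a monolayer),
#'   `"masks"` (read TIFF masks from `input`), or `"features"` (read a
#'   feature CSV from `input`).
#' @param input Input directory (masks mode) or CSV path (features mode).
#' @param generator A [monolayer_params()] object for synthetic mode.
#' @param out_dir Output directory for all artifacts.
#' @param seed Seed recorded in every artifact; overrides the generator
#'   seed so one number controls the whole run.
#' @param stages Stages to run, in dependency order; a stage whose inputs
#'   are unavailable is skipped with an explicit reason.
#' @param n_permutations Permutations for correlation inference.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "masks", "features"),
                       input = NULL,
                       generator = monolayer_params(),
                       out_dir = tempfile("nucmorph_run_"),
                       seed = 1L,
                       stages = c("generate", "features", "fits",
                                  "correlations", "radial", "multivar"),
                       n_permutations = 1000) {
  mode <- match.arg(mode)
  if (mode != "synthetic" && is.null(input)) {
    abort(sprintf("mode `%s` requires `input`.", mode))
  }
  seed <- check_count(seed, "seed", 0L)
  n_permutations <- check_count(n_permutations, "n_permutations", 1L)
  structure(
    list(mode = mode, input = input, generator = generator,
         out_dir = out_dir, seed = seed, stages = stages,
         n_permutations = n_permutations),
    class = "run_config"
  )
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order — generate (or load),
#' feature extraction and filtering, distribution fits, correlation
#' statistics, radial chromatin statistics, multivariable prediction —
#' writing each artifact under `config$out_dir` and returning a manifest
#' listing every artifact with its MD5 content hash. Identical config and
#' seed reproduce identical artifacts; a stage whose upstream input is
#' missing is skipped with an explicit reason in the manifest.
#'
#' @param config A [run_config()] object.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("`config` must be created with `run_config()`.")
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(mode = config$mode, seed = config$seed, stages = list())
  art <- function(files) {
    lapply(stats::setNames(files, basename(files)), function(f) {
      unname(tools::md5sum(f))
    })
  }
  done <- function(stage, files, extra = NULL) {
    manifest$stages[[stage]] <<- c(
      list(status = "done", artifacts = art(files)), extra
    )
  }
  skip <- function(stage, reason) {
    manifest$stages[[stage]] <<- list(status = "skipped", reason = reason)
  }

  mono <- NULL
  features <- NULL

  # --- generate / load -------------------------------------------------
  if ("generate" %in% config$stages) {
    if (config$mode == "synthetic") {
      par <- config$generator
      par$seed <- config$seed
      mono <- generate_monolayer(par)
      mdir <- file.path(out, "monolayer")
      write_monolayer(mono, mdir)
      done("generate", list.files(mdir, full.names = TRUE))
    } else if (config$mode == "masks") {
      mono <- read_monolayer(config$input)
      skip("generate", "input mode is `masks`: monolayer read, not generated")
    } else {
      skip("generate", "input mode is `features`: no masks")
    }
  }
  if (config$mode == "features") {
    features <- as_tibble(utils::read.csv(config$input))
  }

  # --- features --------------------------------------------------------
  if ("features" %in% config$stages) {
    if (!is.null(mono)) {
      records <- extract_features(mono)
      features <- match_and_filter(records)
      fcsv <- file.path(out, "features.csv")
      utils::write.csv(as.data.frame(features), fcsv, row.names = FALSE)
      rjson <- file.path(out, "reconciliation.json")
      jsonlite::write_json(
        c(attr(features, "exclusions")["n_in"],
          attr(features, "exclusions")["n_out"],
          attr(features, "exclusions")["n_edge"],
          attr(features, "exclusions")["n_mitotic"],
          list(seed = config$seed)),
        rjson, auto_unbox = TRUE, digits = NA
      )
      done("features", c(fcsv, rjson))
    } else if (!is.null(features)) {
      skip("features", "feature table supplied directly; nothing to extract")
    } else {
      skip("features", "no masks")
    }
  }

  if (is.null(features)) {
    for (st in intersect(config$stages,
                         c("fits", "correlations", "multivar"))) {
      skip(st, "no feature table")
    }
  }

  # --- distribution fits ----------------------------------------------
  if ("fits" %in% config$stages && !is.null(features)) {
    fits <- list(seed = config$seed)
    if ("cell_area" %in% names(features) && nrow(features) >= 10) {
      f <- fit_lognormal(normalize_areas(features$cell_area))
      fits$cell_area_lognormal <- as.list(glance(f))
    }
    if ("nucleus_area" %in% names(features) && nrow(features) >= 10) {
      f <- fit_lognormal(normalize_areas(features$nucleus_area))
      fits$nucleus_area_lognormal <- as.list(glance(f))
    }
    if ("cell_aspect_ratio" %in% names(features) && nrow(features) >= 10) {
      f <- fit_unit_mean_gamma(rescale_ar(features$cell_aspect_ratio))
      fits$cell_ar_gamma <- as.list(glance(f))
    }
    if (length(fits) > 1) {
      fjson <- file.path(out, "fits.json")
      jsonlite::write_json(fits, fjson, auto_unbox = TRUE, digits = NA)
      done("fits", fjson)
    } else {
      skip("fits", "required feature columns absent or too few records")
    }
  }

  # --- correlations ----------------------------------------------------
  if ("correlations" %in% config$stages && !is.null(features)) {
    pairs <- list(c("cell_area", "nucleus_area"),
                  c("cell_area", "cell_aspect_ratio"),
                  c("cell_aspect_ratio", "nucleus_aspect_ratio"))
    marks <- grep("_norm$", names(features), value = TRUE)
    for (mk in marks) pairs <- c(pairs, list(c("nucleus_area", mk)))
    pairs <- purrr::keep(pairs, function(p) {
      all(p %in% names(features))
    })
    if (length(pairs) > 0 && nrow(features) >= 3) {
      reports <- purrr::map(pairs, function(p) {
        correlate(features[[p[1]]], features[[p[2]]],
                  n_permutations = config$n_permutations,
                  seed = config$seed, names = p)
      })
      ctab <- fdr_monte_carlo(reports,
                              n_permutations = config$n_permutations,
                              seed = config$seed)
      details <- purrr::map_dfr(reports, tidy)
      ctab <- dplyr::left_join(
        details, ctab[c("x_name", "y_name", "fdr")],
        by = c("x_name", "y_name")
      )
      ccsv <- file.path(out, "correlations.csv")
      utils::write.csv(as.data.frame(ctab), ccsv, row.names = FALSE)
      done("correlations", ccsv)
    } else {
      skip("correlations", "no analyzable variable pairs")
    }
  }

  # --- radial ----------------------------------------------------------
  if ("radial" %in% config$stages) {
    if (!is.null(mono) && length(mono$channels) > 1) {
      marks <- setdiff(names(mono$channels), "DAPI")
      rtabs <- purrr::map_dfr(marks, function(ch) {
        st <- radial_stat(mono, ch)
        st$channel <- ch
        st
      })
      rcsv <- file.path(out, "radial.csv")
      utils::write.csv(as.data.frame(rtabs), rcsv, row.names = FALSE)
      done("radial", rcsv)
    } else {
      skip("radial", "no masks")
    }
  }

  # --- multivariable ---------------------------------------------------
  if ("multivar" %in% config$stages && !is.null(features)) {
    cellp <- intersect(CELL_MORPH_FEATURES, names(features))
    nucp <- intersect(NUCLEUS_MORPH_FEATURES, names(features))
    marks <- grep("_norm$", names(features), value = TRUE)
    if (length(cellp) >= 2 && "nucleus_area" %in% names(features) &&
        nrow(features) >= 30) {
      mv <- list(seed = config$seed)
      pr <- predict_target(features, "nucleus_area", cellp,
                           model = "linear", seed = config$seed)
      mv$nucleus_area_from_cell <- as.list(glance(pr))
      if (length(marks) > 0 && length(nucp) >= 2) {
        tgt <- marks[1]
        prm <- predict_target(
          features, tgt, c(nucp, intersect(NC_RATIO_FEATURES,
                                           names(features))),
          model = "linear", seed = config$seed
        )
        mv$mark_from_nucleus <- as.list(glance(prm))
        imp <- dropout_importance(
          features, tgt, c(nucp, intersect(NC_RATIO_FEATURES,
                                           names(features))),
          model = "linear", seed = config$seed
        )
        icsv <- file.path(out, "importance.csv")
        utils::write.csv(as.data.frame(imp), icsv, row.names = FALSE)
      }
      mjson <- file.path(out, "multivar.json")
      jsonlite::write_json(mv, mjson, auto_unbox = TRUE, digits = NA)
      files <- mjson
      if (file.exists(file.path(out, "importance.csv"))) {
        files <- c(files, file.path(out, "importance.csv"))
      }
      done("multivar", files)
    } else {
      skip("multivar", "not enough predictors or records")
    }
  }

  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
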