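#' Run the translation-state analysis pipeline from a config
#'
#' Config-driven orchestration of the synthetic cohort, FRP quantification,
#' relative phenotypes, group test, phenotype correlations and mouse
#' clustering. Every output file is written under `out` and listed, with an
#' MD5 checksum, in a JSON run manifest; the run is deterministic given the
#' global seed, which is fanned out to per-stage child seeds by stage index
#' so stages can be rerun in isolation.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised keys: `seed` (integer, default 1), `out` (output directory),
#'   `stages` (subset of simulate_cohort, frp, phenotype, cluster; default
#'   all), `cohort` (arguments for [simulate_cohort()]), `segmentation`
#'   (arguments for [segment_peaks()]), `cluster_k` (flat clusters, default
#'   2). Unknown keys are rejected.
#' @param out Output directory; overrides `config$out`.
#' @return Invisibly, a list with `results` (in-memory stage outputs) and
#'   `manifest` (stages run, seeds, files with checksums).
#' @export
run_pipeline <- function(config = list(), out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out", "stages", "cohort", "segmentation", "cluster_k")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- out %||% config$out %||% tempfile("polytrans_run_")
  stages <- config$stages %||% c("simulate_cohort", "frp", "phenotype", "cluster")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(seed = seed, stages = character(), files = list())
  results <- list()
  record <- function(path) {
    manifest$files[[basename(path)]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(name, fun) {
    manifest$stages <<- c(manifest$stages, name)
    tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "polytrans_stage_error",
            manifest = manifest)
    })
  }

  if ("simulate_cohort" %in% stages) {
    run_stage("simulate_cohort", function() {
      args <- config$cohort %||% list()
      args$seed <- seed + 1L
      results$cohort <<- do.call(simulate_cohort, args)
      pheno_path <- file.path(out_dir, "phenotypes.tsv")
      readr::write_tsv(results$cohort$phenotypes, pheno_path, progress = FALSE)
      record(pheno_path)
      prof_dir <- file.path(out_dir, "profiles")
      dir.create(prof_dir, showWarnings = FALSE)
      for (id in names(results$cohort$profiles)) {
        p <- file.path(prof_dir, paste0(id, ".tsv"))
        write_profile(results$cohort$profiles[[id]], p)
        record(p)
      }
    })
  }

  if ("frp" %in% stages) {
    run_stage("frp", function() {
      if (is.null(results$cohort)) abort("frp stage needs simulate_cohort output")
      seg_args <- config$segmentation %||% list()
      frp <- purrr::map_dfr(results$cohort$profiles, function(pr) {
        do.call(profile_frp, c(list(pr), seg_args))
      })
      frp <- rename(frp, mouse_id = "sample")
      results$frp <<- frp
      p <- file.path(out_dir, "frp_results.tsv")
      readr::write_tsv(frp, p, progress = FALSE)
      record(p)
    })
  }

  if ("phenotype" %in% stages) {
    run_stage("phenotype", function() {
      if (is.null(results$frp)) abort("phenotype stage needs frp output")
      ph <- relative_phenotype(results$cohort$phenotypes)
      merged <- left_join(ph, select(results$frp, "mouse_id", "frp"),
                          by = "mouse_id")
      results$phenotypes <<- merged
      groups <- unique(merged$genotype)
      test <- compare_frp(merged$frp[merged$genotype == groups[1]],
                          merged$frp[merged$genotype == groups[2]])
      results$frp_test <<- test
      p1 <- file.path(out_dir, "group_tests.tsv")
      readr::write_tsv(tidy(test), p1, progress = FALSE); record(p1)
      cors <- bind_rows(
        mutate(correlate_phenotype(merged, frp, weight_g), phenotype = "weight_g"),
        mutate(correlate_phenotype(merged, frp, righting_s), phenotype = "righting_s")
      )
      results$correlations <<- cors
      p2 <- file.path(out_dir, "correlations.tsv")
      readr::write_tsv(cors, p2, progress = FALSE); record(p2)
    })
  }

  if ("cluster" %in% stages) {
    run_stage("cluster", function() {
      if (is.null(results$phenotypes)) abort("cluster stage needs phenotype output")
      cl <- cluster_mice(results$phenotypes, k = config$cluster_k %||% 2)
      results$clustering <<- cl
      p <- file.path(out_dir, "clustering.json")
      jsonlite::write_json(
        list(merge = cl$hclust$merge, height = cl$hclust$height,
             order = cl$hclust$order, labels = cl$hclust$labels,
             clusters = cl$labels),
        p, auto_unbox = FALSE, digits = NA)
      record(p)
    })
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest,
                 manifest_path = mpath, out = out_dir))
}

profile_schema_check <- function(df, path) {
  req <- c("position", "absorbance", "fraction_index")
  if (!all(req %in% names(df))) {
    return(sprintf("missing column(s): %s", paste(setdiff(req, names(df)), collapse = ", ")))
  }
  bad <- which(diff(df$position) <= 0)
  if (length(bad) > 0) return(sprintf("positions not strictly increasing at row %d", bad[1] + 1L))
  ""
}

pheno_schema_check <- function(df, path) {
  req <- c("mouse_id", "genotype", "stage", "weight_g", "righting_s")
  if (!all(req %in% names(df))) {
    return(sprintf("missing column(s): %s", paste(setdiff(req, names(df)), collapse = ", ")))
  }
  if (any(df$righting_s > 30 + 1e-9)) {
    return(sprintf("righting_s exceeds the 30 s assay cap at row %d",
                   which(df$righting_s > 30)[1]))
  }
  ""
}

cosed_schema_check <- function(df, path) {
  req <- c("protein", "sample", "fraction_index", "intensity")
  if (!all(req %in% names(df))) {
    return(sprintf("missing column(s): %s", paste(setdiff(req, names(df)), collapse = ", ")))
  }
  if (any(df$intensity < 0)) {
    return(sprintf("negative intensity at row %d", which(df$intensity < 0)[1]))
  }
  ""
}

ct_schema_check <- function(df, path) {
  req <- c("gene", "sample", "compartment", "ct")
  if (!all(req %in% names(df))) {
    return(sprintf("missing column(s): %s", paste(setdiff(req, names(df)), collapse = ", ")))
  }
  if (any(df$ct <= 0)) return(sprintf("nonpositive Ct at row %d", which(df$ct <= 0)[1]))
  ""
}

#' Validate pipeline input files against their schemas
#'
#' Report-only: every file gets a pass/fail row with a row-level diagnostic;
#' nothing is thrown. Schemas are guessed from columns unless given.
#'
#' @param paths Character vector of TSV/CSV files.
#' @param schemas Optional character vector (recycled) naming each file's
#'   schema: profile, phenotype, cosed, ct.
#' @return Tibble (file, schema, pass, message).
#' @export
validate_inputs <- function(paths, schemas = NULL) {
  checkers <- list(profile = profile_schema_check, phenotype = pheno_schema_check,
                   cosed = cosed_schema_check, ct = ct_schema_check)
  if (!is.null(schemas)) schemas <- rep_len(schemas, length(paths))
  purrr::map_dfr(seq_along(paths), function(i) {
    path <- paths[i]
    res <- tryCatch({
      df <- suppressWarnings(
        readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
      probs <- readr::problems(df)
      if (nrow(probs) > 0) {
        list(schema = schemas[i] %||% NA_character_,
             msg = sprintf("parse failure at row %d: %s", probs$row[1],
                           probs$expected[1]))
      } else {
        schema <- schemas[i] %||% {
          hits <- names(checkers)[purrr::map_lgl(checkers, function(f) {
            !grepl("missing column", f(df, path)) || FALSE
          })]
          guess <- c(profile = all(c("position", "absorbance") %in% names(df)),
                     phenotype = "mouse_id" %in% names(df),
                     cosed = all(c("protein", "intensity") %in% names(df)),
                     ct = "ct" %in% names(df))
          if (any(guess)) names(guess)[which(guess)[1]] else NA_character_
        }
        if (is.na(schema)) {
          list(schema = schema, msg = "unrecognised schema")
        } else {
          list(schema = schema, msg = checkers[[schema]](df, path))
        }
      }
    }, error = function(e) {
      list(schema = schemas[i] %||% NA_character_,
           msg = sprintf("unreadable: %s", conditionMessage(e)))
    })
    tibble(file = path, schema = res$schema,
           pass = identical(res$msg, ""), message = res$msg)
  })
}
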