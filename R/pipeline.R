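## Pipeline orchestrator: run the full analysis (covariation scans over
## several property scales, CAPS intra-/intermolecular scans, mirrortree
## cross-table with negative control) from one declarative config, writing
## every result table under an output directory.

#' Run the full coevolution analysis from a config
#'
#' The config (an R list, or a path to a YAML file with the same structure)
#' has three parts:
#'
#' * `families`: named list; each entry has `path` (FASTA) or `alignment`
#'   (an [aa_alignment()]), optional `reference` id and optional `domains`
#'   (list of `name`/`start`/`end` entries).
#' * `analyses`: any of
#'   * `covariation`: `family`, optional `scales` (default all built-ins),
#'     `confidence`, `variability_min`, `cluster_cutoff`;
#'   * `caps`: `family`, optional `family2` + `species_map` for an
#'     intermolecular scan, `alpha`, `n_resample`, `min_R`, `group_cap`;
#'   * `mirrortree`: `ligands`, `receptors` (names of families, or named
#'     lists mapping table names to `family`/`domain`), optional `control`,
#'     `deletion`.
#' * `seed`: global seed; each analysis derives its own seed from it and the
#'   analysis name, so adding an analysis never perturbs the others.
#'
#' Every analysis writes its tables (TSV; cluster trees as Newick) under
#' `out_dir` and is recorded in the returned report; a failing analysis is
#' recorded with its error message and does not abort the others.
#'
#' @param config List or path to a YAML config.
#' @param out_dir Output directory (created if missing). Defaults to
#'   `config$out_dir` or a temporary directory.
#' @return Object of class `run_report`: list with `outputs` (named list of
#'   written file paths per analysis), `results` (the in-memory result
#'   objects), `errors` (named character vector of failure reasons),
#'   `warnings`, `seed` and `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_path <- NA_character_
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$families) || length(config$families) == 0L) {
    stop("config must declare at least one family")
  }
  if (is.null(config$analyses) || length(config$analyses) == 0L) {
    stop("config must declare at least one analysis")
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("coevoscan_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  families <- lapply(config$families, load_family)
  names(families) <- names(config$families)

  outputs <- list(); results <- list()
  errors <- character(0); warn_log <- character(0)
  for (aname in names(config$analyses)) {
    spec <- config$analyses[[aname]]
    akind <- sub("_.*$", "", aname)  # covariation_vol etc. -> covariation
    res <- withCallingHandlers(
      tryCatch({
        set.seed(derive_seed(seed, aname))
        switch(akind,
          covariation = run_covariation_block(spec, families, out_dir, aname),
          caps = run_caps_block(spec, families, out_dir, aname,
                                derive_seed(seed, aname)),
          mirrortree = run_mirrortree_block(spec, families, out_dir, aname),
          stop("unknown analysis kind: ", akind))
      }, error = function(e) structure(conditionMessage(e), class = "run_error")),
      warning = function(w) {
        warn_log <<- c(warn_log, paste0(aname, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "run_error")) {
      errors[aname] <- as.character(res)
    } else {
      outputs[[aname]] <- res$files
      results[[aname]] <- res$result
    }
  }
  if (length(errors) == length(config$analyses)) {
    stop("all analyses failed: ", paste(errors, collapse = "; "))
  }
  structure(list(outputs = outputs, results = results, errors = errors,
                 warnings = warn_log, seed = seed,
                 provenance = list(
                   config_path = cfg_path,
                   config_md5 = if (!is.na(cfg_path))
                     unname(tools::md5sum(cfg_path)) else NA_character_,
                   package_version =
                     as.character(utils::packageVersion("coevoscan")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "run_report")
}

## Per-analysis seeds: global seed plus a stable hash of the analysis name,
## kept within 32-bit integer range.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100003L
  (as.integer(seed) * 1009L + h) %% .Machine$integer.max
}

load_family <- function(entry) {
  aln <- if (!is.null(entry$alignment)) {
    a <- entry$alignment
    if (!is.null(entry$reference)) a$reference_id <- entry$reference
    a
  } else if (!is.null(entry$path)) {
    read_alignment(entry$path, reference_id = entry$reference)
  } else {
    stop("family entry needs 'path' or 'alignment'")
  }
  doms <- NULL
  if (!is.null(entry$domains)) {
    doms <- lapply(entry$domains, function(e)
      domain_annotation(e$name, e$start, e$end))
    names(doms) <- vapply(doms, `[[`, character(1), "name")
    check_domains(doms, allow_overlap = isTRUE(entry$allow_overlap))
  }
  list(alignment = aln, domains = doms)
}

get_family <- function(families, name) {
  if (!name %in% names(families)) stop("unknown family: ", name)
  families[[name]]
}

## Resolve a mirrortree form: either a family name or a list with
## family/domain, returning the (possibly domain-sliced) alignment.
resolve_form <- function(entry, families) {
  if (is.character(entry)) return(get_family(families, entry)$alignment)
  fam <- get_family(families, entry$family)
  aln <- fam$alignment
  if (!is.null(entry$domain)) {
    if (is.null(fam$domains) || !entry$domain %in% names(fam$domains)) {
      stop("unknown domain '", entry$domain, "' for family ", entry$family)
    }
    aln <- slice_domain(aln, fam$domains[[entry$domain]])
  }
  aln
}

run_covariation_block <- function(spec, families, out_dir, aname) {
  fam <- get_family(families, spec$family)
  scales <- spec$scales
  if (is.null(scales)) {
    scales <- c("volume", "hydrophobicity", "polarity", "flexibility")
  }
  confidence <- if (is.null(spec$confidence)) 0.99 else spec$confidence
  vmin <- if (is.null(spec$variability_min)) 3L else spec$variability_min
  cutoff <- if (is.null(spec$cluster_cutoff)) 0.55 else spec$cluster_cutoff

  files <- character(0); res <- list()
  for (sc in scales) {
    scan <- covariation_scan(fam$alignment, aa_scale(sc),
                             confidence = confidence, variability_min = vmin)
    f <- file.path(out_dir, paste0(aname, "_", sc, "_pairs.tsv"))
    write_covariation_tsv(scan, f, domains = fam$domains)
    files <- c(files, f)
    if (length(scan$positions) >= 2L) {
      cl <- cluster_positions(scan, cutoff = cutoff)
      fn <- file.path(out_dir, paste0(aname, "_", sc, "_clusters.nwk"))
      writeLines(cl$newick, fn)
      files <- c(files, fn)
    }
    if (!is.null(fam$domains)) {
      ds <- domain_pair_summary(scan, fam$domains)
      fd <- file.path(out_dir, paste0(aname, "_", sc, "_domain_summary.tsv"))
      write_domain_summary_tsv(ds, fd)
      files <- c(files, fd)
    }
    res[[sc]] <- scan
  }
  list(files = files, result = res)
}

run_caps_block <- function(spec, families, out_dir, aname, seed) {
  fam <- get_family(families, spec$family)
  n_resample <- if (is.null(spec$n_resample)) 1000L else spec$n_resample
  alpha <- if (is.null(spec$alpha)) 0.05 else spec$alpha
  min_R <- if (is.null(spec$min_R)) 0.1 else spec$min_R
  group_cap <- if (is.null(spec$group_cap)) 0.05 else spec$group_cap
  if (!is.null(spec$family2)) {
    fam2 <- get_family(families, spec$family2)
    smap <- if (!is.null(spec$species_map)) unlist(spec$species_map) else NULL
    scan <- caps_intermolecular(fam$alignment, fam2$alignment,
                                species_map = smap, n_resample = n_resample,
                                alpha = alpha, min_R = min_R, seed = seed)
  } else {
    scan <- caps_scan(fam$alignment, n_resample = n_resample, alpha = alpha,
                      min_R = min_R, group_cap = group_cap, seed = seed)
  }
  f1 <- file.path(out_dir, paste0(aname, "_pairs.tsv"))
  f2 <- file.path(out_dir, paste0(aname, "_groups.tsv"))
  write_caps_tsv(scan, f1)
  write_caps_groups_tsv(scan, f2)
  list(files = c(f1, f2), result = scan)
}

run_mirrortree_block <- function(spec, families, out_dir, aname) {
  form_names <- function(entries) {
    if (!is.null(names(entries)) && all(names(entries) != "")) {
      return(names(entries))
    }
    vapply(entries, function(e) {
      if (is.character(e)) e else e$family
    }, character(1))
  }
  ligands <- lapply(spec$ligands, resolve_form, families = families)
  names(ligands) <- form_names(spec$ligands)
  receptors <- lapply(spec$receptors, resolve_form, families = families)
  names(receptors) <- form_names(spec$receptors)
  control <- if (is.null(spec$control)) NULL else {
    resolve_form(spec$control, families)
  }
  deletion <- if (is.null(spec$deletion)) "pairwise" else spec$deletion
  smap <- if (is.null(spec$species_map)) NULL else {
    lapply(spec$species_map, unlist)
  }
  tab <- correlation_table(ligands, receptors, control = control,
                           deletion = deletion, species_map = smap)
  f <- file.path(out_dir, paste0(aname, "_table.tsv"))
  write_mirrortree_tsv(tab, f)
  list(files = f, result = tab)
}

#' Write a domain-pair summary as TSV
#'
#' One row per domain-by-domain cell with positive, negative and total
#' significant-pair counts.
#'
#' @param x A `domain_pair_summary`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_summary_tsv <- function(x, path) {
  dn <- rownames(x$total)
  grid <- expand.grid(domain1 = dn, domain2 = dn, stringsAsFactors = FALSE)
  grid <- grid[match(grid$domain1, dn) <= match(grid$domain2, dn), ]
  out <- data.frame(grid,
                    positive = x$positive[cbind(grid$domain1, grid$domain2)],
                    negative = x$negative[cbind(grid$domain1, grid$domain2)],
                    total = x$total[cbind(grid$domain1, grid$domain2)])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d analyses ok, %d failed (seed %d)\n",
              length(x$outputs), length(x$errors), x$seed))
  for (nm in names(x$outputs)) {
    cat("  ", nm, ": ", paste(basename(x$outputs[[nm]]), collapse = ", "),
        "\n", sep = "")
  }
  for (nm in names(x$errors)) {
    cat("  ", nm, " FAILED: ", x$errors[nm], "\n", sep = "")
  }
  invisible(x)
}
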