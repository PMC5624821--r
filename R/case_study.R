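#' Default case-study configuration
#'
#' Flat list of settings consumed by [run_case_study()]. Without input
#' files the pipeline analyses a self-simulated population (default 25
#' individuals, 377 microsatellite-like markers with 10 alleles) so it runs
#' with no external data. Simulated-pair counts per relationship control
#' the hull sizes.
#'
#' @param ... overrides of the defaults.
#' @return A named list.
#' @export
case_study_config <- function(...) {
  cfg <- list(
    ped = NULL, map = NULL, table = NULL,     # input files (optional)
    n_individuals = 25, n_markers = 377, n_alleles = 10,
    freq_mode = "dirichlet",                  # or "equifrequent"
    dirichlet_alpha = 1,
    missing_sentinel = NULL,
    min_informative = 50,
    tol = 1e-7, max_iter = 2000, corner_starts = FALSE,
    constrain = FALSE, loo_pair = FALSE,
    n_po = 80, n_fs = 48, n_hs = 40, n_av = 40, n_gg = 40,
    n_fc = 36, n_un = 250,
    unrelated_threshold = 0.2,
    seed = 1, out_dir = "relkit-case-study",
    plots = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  utils::modifyList(cfg, over)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' values are parsed as numbers where possible. Keys must be known to
#' [case_study_config()]; file values are overridden by arguments passed
#' directly to [run_case_study()].
#'
#' @param path file path.
#' @return A named list of settings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("TRUE", "FALSE")) as.logical(v) else v
  })
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Run the full relatedness pipeline on one dataset
#'
#' Chains every stage of the package on a genotype matrix (read from files
#' named in the config, or self-simulated): pairwise IBS statistics, EM
#' Cotterman estimates, selection of an unrelated founder subset,
#' gene-dropped artificial pairs per relationship, convex hulls in each
#' coordinate system, the four graphic families, and a manifest recording
#' seed and settings. Deterministic given the same config.
#'
#' @param config list from [case_study_config()] or a path to a flat
#'   key = value file ([read_run_config()]).
#' @param ... overrides applied on top of `config`.
#' @return The output directory, invisibly. Files written: `pairs.tsv`
#'   (combined per-pair table), `ibd.tsv`, `hulls_<space>.tsv`,
#'   `fig_<kind>.png` (if `plots`), `manifest.json`.
#' @export
run_case_study <- function(config = case_study_config(), ...) {
  if (is.character(config)) config <- do.call(case_study_config, read_run_config(config))
  config <- utils::modifyList(config, list(...))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("case-study stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  set.seed(cfg$seed)

  G <- stage("input", {
    if (!is.null(cfg$ped)) {
      read_ped(cfg$ped, cfg$map)
    } else if (!is.null(cfg$table)) {
      read_genotypes(cfg$table, cfg$missing_sentinel)
    } else {
      f <- if (cfg$freq_mode == "equifrequent") {
        rep(1 / cfg$n_alleles, cfg$n_alleles)
      } else {
        NULL
      }
      fr <- if (is.null(f)) {
        allele_freqs(lapply(seq_len(cfg$n_markers), function(j) {
          w <- stats::rgamma(cfg$n_alleles, shape = cfg$dirichlet_alpha)
          w / sum(w)
        }), cfg$n_markers)
      } else {
        allele_freqs(f, cfg$n_markers)
      }
      simulate_founders(cfg$n_individuals, fr,
                        ids = paste0("I", seq_len(cfg$n_individuals)))
    }
  })

  freqs <- stage("allele-freqs", estimate_allele_freqs(G))
  pairs <- stage("ibs-ibd", suppressWarnings(
    pair_statistics(G, freqs = freqs, min_informative = cfg$min_informative,
                    tol = cfg$tol, max_iter = cfg$max_iter,
                    corner_starts = cfg$corner_starts,
                    constrain = cfg$constrain, loo_pair = cfg$loo_pair)))
  write_pair_table(pairs, file.path(cfg$out_dir, "pairs.tsv"))
  readr::write_tsv(pairs, file.path(cfg$out_dir, "ibd.tsv"), progress = FALSE)

  un_ids <- stage("unrelated-subset",
                  select_unrelated(G, ibd = pairs, threshold = cfg$unrelated_threshold))
  keep <- match(un_ids, G$individual_ids)
  founders <- genotype_matrix(G$alleles[keep, , , drop = FALSE], un_ids, G$marker_ids)

  counts <- c(PO = cfg$n_po, FS = cfg$n_fs, HS = cfg$n_hs, AV = cfg$n_av,
              GG = cfg$n_gg, FC = cfg$n_fc, UN = cfg$n_un)
  sims <- stage("simulate", purrr::imap(counts[counts > 0], function(np, rel) {
    suppressWarnings(
      simulate_pairs(rel, np, freqs, founders = founders,
                     tol = cfg$tol, max_iter = cfg$max_iter))
  }))
  sim_stats <- dplyr::bind_rows(purrr::map(sims, "stats"))
  readr::write_tsv(sim_stats, file.path(cfg$out_dir, "simulated_pairs.tsv"),
                   progress = FALSE)

  spaces <- c("msd", "k_scatter", "ternary_p", "ternary_k", "ilr_p", "ilr_k")
  hulls <- stage("hulls", {
    hl <- purrr::map(spaces, function(sp) purrr::map(sims, hulls_for, space = sp))
    names(hl) <- spaces
    for (sp in spaces) {
      df <- purrr::map_dfr(hl[[sp]], function(h) {
        dplyr::mutate(h$vertices, relationship = h$relationship)
      })
      readr::write_tsv(df, file.path(cfg$out_dir, paste0("hulls_", sp, ".tsv")),
                       progress = FALSE)
    }
    hl
  })

  if (isTRUE(cfg$plots)) {
    stage("plots", {
      mplot <- plot_msd(pairs, domain = msd_domain(min(n_markers(G), 500)),
                        m = n_markers(G), hulls = hulls$msd)
      ggplot2::ggsave(file.path(cfg$out_dir, "fig_msd.png"), mplot,
                      width = 6, height = 5, dpi = 150)
      ggplot2::ggsave(file.path(cfg$out_dir, "fig_k_scatter.png"),
                      plot_pair_scatter(pairs, "k", 0, 1, hulls = hulls$k_scatter),
                      width = 6, height = 5, dpi = 150)
      ggplot2::ggsave(file.path(cfg$out_dir, "fig_ternary_k.png"),
                      plot_ternary(pairs, "k", hulls = hulls$ternary_k),
                      width = 6, height = 5, dpi = 150)
      ggplot2::ggsave(file.path(cfg$out_dir, "fig_ilr_k.png"),
                      plot_ilr(pairs, "k", hulls = hulls$ilr_k),
                      width = 6, height = 5, dpi = 150)
    })
  }

  manifest <- list(
    package = "relkit",
    version = as.character(utils::packageVersion("relkit")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    settings = cfg[setdiff(names(cfg), c("out_dir"))],
    n_individuals = n_individuals(G),
    n_markers = n_markers(G),
    n_pairs = nrow(pairs),
    n_unrelated_founders = length(un_ids)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(cfg$out_dir)
}
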