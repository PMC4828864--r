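# End-to-end orchestration: scan -> ontology filter -> scoring/ranking,
# plus optional variability and imaging arms, driven by one YAML config.
# Stage outputs are pure functions of inputs + config; a second run with
# the same config writes byte-identical files.

#' Run the full analysis pipeline from a config
#'
#' Config (YAML file or equivalent list) layout:
#' \preformatted{
#' stages:  {scan: yes, filter: yes, score: yes, variability: no, imaging: no}
#' inputs:
#'   panels: dir/of/aligned/*.fasta    # one ortholog panel per protein
#'   annotations: annotations.tsv      # id, accession, terms
#'   matrix: BLOSUM100.txt             # omit to use the bundled BLOSUM100
#'   variants: variants.tsv            # gene, class (variability arm)
#'   images: dir/of/{*_green,*_red}.png  # imaging arm, paired channels
#' params:
#'   consensus_mode: unanimous   # or majority
#'   rank_key: weighted_per_length
#'   single_cell_area: 150
#'   min_area: 100
#'   ignore_case: no
#'   focal_gene: PCDHB11         # variability arm
#' }
#'
#' Stage outputs land in `out_dir` (`substitutions.tsv`,
#' `filtered_proteins.tsv`, `ranking.tsv`, `variability.tsv`,
#' `clusters.tsv`) along with `manifest.json` recording the config hash,
#' package version and per-stage row counts.  A stage failure aborts
#' with an error naming the stage; outputs of completed stages are
#' retained.
#'
#' @param config path to a YAML config file, or a list with the same
#'   structure.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort(sprintf("config file not found: %s", config),
            "humsub_config_error")
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else {
    cfg_hash <- unname(tools::md5sum(
      textConnection_md5(yaml::as.yaml(config))))
  }
  stages <- config$stages %||% list()
  inputs <- config$inputs %||% list()
  params <- config$params %||% list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("humsub")),
                   stages = list())

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "humsub_stage_error")
    })
  }

  subs_by_protein <- NULL
  lengths_by_protein <- NULL

  if (isTRUE(stages$scan)) {
    run_stage("scan", function() {
      files <- sort(list.files(inputs$panels, pattern = "\\.fa(sta)?$",
                               full.names = TRUE))
      if (!length(files))
        abort("no panel FASTA files found", "humsub_config_error")
      mode <- params$consensus_mode %||% "unanimous"
      res <- lapply(files, function(f) {
        panel <- read_panel_fasta(f)
        subs <- find_fixed_substitutions(panel, mode = mode)
        list(protein = panel$protein, length = ungapped_length(panel),
             subs = subs)
      })
      subs_by_protein <<- setNames(lapply(res, `[[`, "subs"),
                                   vapply(res, `[[`, character(1), "protein"))
      lengths_by_protein <<- setNames(vapply(res, `[[`, numeric(1), "length"),
                                      names(subs_by_protein))
      tab <- do.call(rbind, lapply(names(subs_by_protein), function(p) {
        s <- subs_by_protein[[p]]
        if (!nrow(s)) return(NULL)
        cbind(protein = p, s[, c("position", "ancestral", "human")])
      }))
      if (is.null(tab))
        tab <- data.frame(protein = character(), position = integer(),
                          ancestral = character(), human = character())
      write_tsv(tab, file.path(out_dir, "substitutions.tsv"))
      manifest$stages$scan <<- list(proteins = length(files),
                                    substitutions = nrow(tab))
    })
  }

  filtered_ids <- NULL
  if (isTRUE(stages$filter)) {
    run_stage("filter", function() {
      records <- read_annotations(inputs$annotations)
      counts <- if (!is.null(subs_by_protein))
        vapply(subs_by_protein, nrow, integer(1))
      res <- apply_filter(records, substitutions_per_protein = counts,
                          ignore_case = isTRUE(params$ignore_case))
      filtered_ids <<- res$ids
      write_tsv(data.frame(id = res$ids),
                file.path(out_dir, "filtered_proteins.tsv"))
      manifest$stages$filter <<- list(annotated = nrow(records),
                                      selected = res$n_proteins,
                                      with_substitution = res$n_with_substitution)
    })
  }

  if (isTRUE(stages$score)) {
    run_stage("score", function() {
      if (is.null(subs_by_protein))
        abort("scoring needs the scan stage", "humsub_config_error")
      mat <- if (!is.null(inputs$matrix))
        read_score_matrix(inputs$matrix) else blosum100()
      wt <- derive_weights(mat)
      ids <- if (!is.null(filtered_ids))
        intersect(names(subs_by_protein), filtered_ids)
      else names(subs_by_protein)
      scores <- do.call(rbind, lapply(ids, function(p)
        score_protein(subs_by_protein[[p]], lengths_by_protein[[p]], wt,
                      protein = p)))
      ranking <- rank_proteins(scores,
                               key = params$rank_key %||% "weighted_per_length")
      write_tsv(ranking, file.path(out_dir, "ranking.tsv"))
      manifest$stages$score <<- list(scored = nrow(ranking),
                                     top = if (nrow(ranking)) ranking$protein[1]
                                     else NA)
    })
  }

  if (isTRUE(stages$variability)) {
    run_stage("variability", function() {
      variants <- read_variants(inputs$variants)
      counts <- vapply(split(variants, variants$gene),
                       count_variable_positions, integer(1))
      subs <- if (!is.null(subs_by_protein))
        vapply(subs_by_protein, nrow, integer(1))[names(counts)]
      else setNames(rep(NA_integer_, length(counts)), names(counts))
      subs[is.na(subs)] <- 0L
      summ <- cluster_summary(counts, subs, focal = params$focal_gene)
      write_tsv(summ$table, file.path(out_dir, "variability.tsv"))
      manifest$stages$variability <<- list(genes = length(counts),
                                           median = summ$median)
    })
  }

  if (isTRUE(stages$imaging)) {
    run_stage("imaging", function() {
      greens <- sort(list.files(inputs$images, pattern = "_green\\.png$",
                                full.names = TRUE))
      if (!length(greens))
        abort("no *_green.png images found", "humsub_config_error")
      sca <- params$single_cell_area %||% 150
      min_area <- params$min_area %||% 100
      one_channel <- function(path, channel) {
        cl <- extract_clusters(threshold_image(read_channel_png(path))$mask,
                               min_area)
        if (!nrow(cl)) return(NULL)
        cbind(image = basename(path), channel = channel, cl)
      }
      rows <- do.call(rbind, unlist(lapply(greens, function(g) {
        r <- sub("_green\\.png$", "_red.png", g)
        parts <- list(one_channel(g, "green"))
        if (file.exists(r)) parts <- c(parts, list(one_channel(r, "red")))
        parts
      }), recursive = FALSE))
      if (is.null(rows))
        rows <- data.frame(image = character(), channel = character(),
                           cluster = integer(), area = integer())
      rows$class <- if (nrow(rows)) size_class(rows$area, sca) else character()
      write_tsv(rows, file.path(out_dir, "clusters.tsv"))
      manifest$stages$imaging <<- list(images = length(greens),
                                       clusters = nrow(rows))
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of an in-memory string (config given as a list)
textConnection_md5 <- function(text) {
  tmp <- tempfile()
  writeLines(text, tmp)
  tmp
}

# protein length = ungapped length of the reference (first) human haplotype
ungapped_length <- function(panel) {
  sum(strsplit(panel$human[[1]], "")[[1]] != "-")
}
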