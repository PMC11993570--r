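#' Read a signature registry
#'
#' A registry bundles the definitions needed to reconstruct published
#' signatures on a new cohort: radiomic signatures (linear combinations of
#' MRI features with published coefficients, plus a normalization policy)
#' and gene expression signatures (EntrezID-keyed weighted gene sums with a
#' stratification threshold rule). Registries are stored as YAML; the schema
#' is documented in the file shipped at
#' `system.file("extdata", "registry_hnscc_synthetic.yaml", package = "radsig")`.
#'
#' Signatures whose source coefficients or gene lists could not be
#' transcribed are marked `incomplete: true`: they load, appear in the
#' feature census, and can be subset, but scoring them is an error.
#'
#' @param path Path to a registry YAML file.
#' @return An object of class `sig_registry`: a list with elements
#'   `radiomic` (tibble, one row per radiomic signature, list-column `terms`),
#'   `gene` (tibble, one row per gene signature, list-column `genes`) and
#'   `provenance` (path and md5 checksum).
#' @export
#' @examples
#' reg <- read_signature_registry(
#'   system.file("extdata", "registry_hnscc_synthetic.yaml", package = "radsig"))
#' reg
read_signature_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("registry file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || (is.null(raw$radiomic) && is.null(raw$gene))) {
    abort(sprintf("registry file is empty or lacks radiomic/gene sections: %s", path))
  }
  reg <- new_registry(
    radiomic = parse_radiomic_defs(raw$radiomic),
    gene = parse_gene_defs(raw$gene),
    provenance = list(path = normalizePath(path),
                      checksum = unname(tools::md5sum(path)))
  )
  validate_registry(reg)
}

new_registry <- function(radiomic, gene, provenance = list()) {
  structure(list(radiomic = radiomic, gene = gene, provenance = provenance),
            class = "sig_registry")
}

parse_radiomic_defs <- function(x) {
  if (is.null(x)) {
    return(tibble(id = character(), source = character(),
                  normalization = character(), intercept = double(),
                  incomplete = logical(), terms = list()))
  }
  rows <- purrr::map(x, function(d) {
    if (is.null(d$id)) abort("radiomic signature without an `id` field")
    terms <- purrr::map_dfr(d$terms, function(t) {
      tibble(
        modality = as.character(t$modality %||% NA_character_),
        image_filter = as.character(t$image_filter %||% "original"),
        feature_class = as.character(t$feature_class %||% NA_character_),
        feature_name = as.character(t$feature_name %||% NA_character_),
        coefficient = as.numeric(t$coefficient %||% NA_real_)
      )
    })
    tibble(
      id = as.character(d$id),
      source = as.character(d$source %||% NA_character_),
      normalization = as.character(d$normalization %||% "none"),
      intercept = as.numeric(d$intercept %||% 0),
      incomplete = isTRUE(d$incomplete),
      terms = list(terms)
    )
  })
  dplyr::bind_rows(rows)
}

parse_gene_defs <- function(x) {
  if (is.null(x)) {
    return(tibble(id = character(), source = character(),
                  aggregation = character(), threshold_rule = character(),
                  threshold_value = double(), n_genes = integer(),
                  incomplete = logical(), genes = list()))
  }
  rows <- purrr::map(x, function(d) {
    if (is.null(d$id)) abort("gene signature without an `id` field")
    genes <- purrr::map_dfr(d$genes, function(g) {
      tibble(entrez_id = as.integer(g$entrez_id %||% NA_integer_),
             symbol = as.character(g$symbol %||% NA_character_),
             weight = as.numeric(g$weight %||% 1))
    })
    thr <- d$threshold %||% "median"
    if (is.list(thr)) {
      rule <- "fixed"; val <- as.numeric(thr$fixed %||% thr$value %||% NA_real_)
    } else if (is.numeric(thr)) {
      rule <- "fixed"; val <- as.numeric(thr)
    } else {
      rule <- as.character(thr); val <- NA_real_
    }
    tibble(
      id = as.character(d$id),
      source = as.character(d$source %||% NA_character_),
      aggregation = as.character(d$aggregation %||% "weighted_sum"),
      threshold_rule = rule,
      threshold_value = val,
      n_genes = as.integer(d$n_genes %||% nrow(genes)),
      incomplete = isTRUE(d$incomplete),
      genes = list(genes)
    )
  })
  dplyr::bind_rows(rows)
}

validate_registry <- function(reg) {
  r <- reg$radiomic
  if (anyDuplicated(r$id)) {
    abort(sprintf("duplicate radiomic signature id: %s",
                  paste(unique(r$id[duplicated(r$id)]), collapse = ", ")))
  }
  for (i in seq_len(nrow(r))) {
    terms <- r$terms[[i]]
    id <- r$id[i]
    if (nrow(terms) == 0L) abort(sprintf("signature %s has no terms", id))
    bad_mod <- setdiff(terms$modality, admitted_modalities())
    if (length(bad_mod)) {
      abort(sprintf("signature %s uses unknown modality: %s", id,
                    paste(bad_mod, collapse = ", ")))
    }
    if (!r$incomplete[i] && any(!is.finite(terms$coefficient))) {
      abort(sprintf("signature %s has a missing or non-finite coefficient", id))
    }
    keys <- feature_key(terms$modality, terms$image_filter, terms$feature_name)
    if (anyDuplicated(keys)) {
      abort(sprintf("signature %s lists the same feature twice", id))
    }
    if (!r$normalization[i] %in% c("none", "zscore")) {
      abort(sprintf("signature %s: normalization must be `none` or `zscore`", id))
    }
  }
  g <- reg$gene
  if (anyDuplicated(g$id)) {
    abort(sprintf("duplicate gene signature id: %s",
                  paste(unique(g$id[duplicated(g$id)]), collapse = ", ")))
  }
  for (i in seq_len(nrow(g))) {
    genes <- g$genes[[i]]
    id <- g$id[i]
    if (!g$incomplete[i]) {
      if (nrow(genes) == 0L) abort(sprintf("gene signature %s has no genes", id))
      if (g$n_genes[i] != nrow(genes)) {
        abort(sprintf("gene signature %s: n_genes (%d) does not match the gene list (%d)",
                      id, g$n_genes[i], nrow(genes)))
      }
      if (any(!is.finite(genes$weight))) {
        abort(sprintf("gene signature %s has a non-finite weight", id))
      }
      if (any(is.na(genes$entrez_id) | genes$entrez_id <= 0L)) {
        abort(sprintf("gene signature %s has an invalid EntrezID", id))
      }
    }
    if (nrow(genes) && anyDuplicated(genes$entrez_id)) {
      abort(sprintf("gene signature %s lists an EntrezID twice", id))
    }
    if (!g$aggregation[i] %in% "weighted_sum") {
      abort(sprintf("gene signature %s: unsupported aggregation `%s`",
                    id, g$aggregation[i]))
    }
    if (!g$threshold_rule[i] %in% c("median", "fixed")) {
      abort(sprintf("gene signature %s: threshold rule must be `median` or `fixed`",
                    id))
    }
    if (g$threshold_rule[i] == "fixed" && !is.finite(g$threshold_value[i])) {
      abort(sprintf("gene signature %s: fixed threshold without a value", id))
    }
  }
  if (length(intersect(r$id, g$id))) {
    abort("radiomic and gene signature ids overlap")
  }
  reg
}

#' Write a signature registry to YAML
#'
#' Inverse of [read_signature_registry()]: `read_signature_registry()` on the
#' written file reproduces the registry content.
#'
#' @param registry A `sig_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature_registry <- function(registry, path) {
  stopifnot(inherits(registry, "sig_registry"))
  rad <- purrr::pmap(registry$radiomic, function(id, source, normalization,
                                                 intercept, incomplete, terms) {
    out <- list(id = id, source = source, normalization = normalization,
                intercept = intercept,
                terms = purrr::pmap(terms, function(modality, image_filter,
                                                    feature_class, feature_name,
                                                    coefficient) {
                  t <- list(modality = modality, image_filter = image_filter,
                            feature_class = feature_class,
                            feature_name = feature_name)
                  if (is.finite(coefficient)) t$coefficient <- coefficient
                  t
                }))
    if (incomplete) out$incomplete <- TRUE
    out
  })
  gen <- purrr::pmap(registry$gene, function(id, source, aggregation,
                                             threshold_rule, threshold_value,
                                             n_genes, incomplete, genes) {
    out <- list(id = id, source = source, aggregation = aggregation,
                threshold = if (threshold_rule == "fixed")
                  list(fixed = threshold_value) else threshold_rule,
                n_genes = n_genes,
                genes = purrr::pmap(genes, function(entrez_id, symbol, weight) {
                  list(entrez_id = entrez_id, symbol = symbol, weight = weight)
                }))
    if (incomplete) out$incomplete <- TRUE
    out
  })
  yaml::write_yaml(list(radiomic = rad, gene = gen), path)
  invisible(path)
}

#' Census of distinct radiomic features in a registry
#'
#' Feature identity is the triple (modality, image filter, feature name):
#' the same texture feature computed on two MRI sequences counts twice. The
#' census reports the number of distinct constituent features, their split
#' by modality, and the features shared by two or more signatures.
#'
#' @param registry A `sig_registry`.
#' @return A `feature_census` list: `total` (distinct triples),
#'   `per_modality` (tibble of counts), `shared` (tibble of triples used by
#'   two or more signatures, with the signature ids), and `triples` (the full
#'   feature-by-signature table).
#' @export
census_features <- function(registry) {
  stopifnot(inherits(registry, "sig_registry"))
  triples <- purrr::map2_dfr(registry$radiomic$id, registry$radiomic$terms,
    function(id, terms) {
      dplyr::mutate(terms[c("modality", "image_filter", "feature_name")],
                    signature = id)
    })
  if (nrow(triples) == 0L) {
    return(structure(list(total = 0L,
                          per_modality = tibble(modality = character(),
                                                n = integer()),
                          shared = tibble(), triples = triples),
                     class = "feature_census"))
  }
  distinct <- dplyr::summarise(
    dplyr::group_by(triples, .data$modality, .data$image_filter,
                    .data$feature_name),
    signatures = list(sort(unique(.data$signature))),
    n_signatures = dplyr::n_distinct(.data$signature),
    .groups = "drop")
  per_mod <- dplyr::count(distinct, .data$modality, name = "n")
  shared <- dplyr::filter(distinct, .data$n_signatures >= 2L)
  structure(list(total = nrow(distinct),
                 per_modality = per_mod,
                 shared = shared,
                 triples = triples),
            class = "feature_census")
}

#' @export
print.feature_census <- function(x, ...) {
  cat(sprintf("Radiomic feature census: %d distinct (modality, filter, feature) triples\n",
              x$total))
  for (i in seq_len(nrow(x$per_modality))) {
    cat(sprintf("  %-8s %d\n", x$per_modality$modality[i], x$per_modality$n[i]))
  }
  if (nrow(x$shared)) {
    cat(sprintf("Shared by >= 2 signatures: %d\n", nrow(x$shared)))
    for (i in seq_len(nrow(x$shared))) {
      cat(sprintf("  %s (%s) in %s\n", x$shared$feature_name[i],
                  x$shared$modality[i],
                  paste(x$shared$signatures[[i]], collapse = ", ")))
    }
  } else {
    cat("No feature is shared between signatures\n")
  }
  invisible(x)
}

#' Subset a registry by signature id
#'
#' @param registry A `sig_registry`.
#' @param ids Character vector of radiomic and/or gene signature ids; order
#'   is preserved within each list.
#' @return A `sig_registry` containing only the requested signatures.
#' @export
subset_registry <- function(registry, ids) {
  stopifnot(inherits(registry, "sig_registry"))
  known <- c(registry$radiomic$id, registry$gene$id)
  missing <- setdiff(ids, known)
  if (length(missing)) {
    abort(sprintf("unknown signature id: %s", paste(missing, collapse = ", ")))
  }
  new_registry(
    radiomic = registry$radiomic[registry$radiomic$id %in% ids, ],
    gene = registry$gene[registry$gene$id %in% ids, ],
    provenance = registry$provenance
  )
}

#' @export
print.sig_registry <- function(x, ...) {
  n_inc_r <- sum(x$radiomic$incomplete)
  n_inc_g <- sum(x$gene$incomplete)
  cat(sprintf("<sig_registry> %d radiomic, %d gene signatures\n",
              nrow(x$radiomic), nrow(x$gene)))
  if (n_inc_r + n_inc_g > 0) {
    cat(sprintf("  incomplete (not scorable): %d radiomic, %d gene\n",
                n_inc_r, n_inc_g))
  }
  if (!is.null(x$provenance$path)) {
    cat(sprintf("  source: %s\n", x$provenance$path))
  }
  invisible(x)
}

# Path to the registry shipped with the package (printed structure of the
# seven MRI signatures and 29 immune signatures; synthetic feature names
# where the source supplements are not transcribed).
#' Path to the shipped HNSCC signature registry
#'
#' The shipped registry transcribes the printed structure of the seven MRI
#' radiomic prognostic signatures (feature counts per modality, normalization
#' fallback, the single feature shared between R6 and R7) and the 29
#' immune-related gene expression signatures (declared gene counts; the full
#' 31-gene radiosensitivity signature G8). Feature names and the non-G8 gene
#' lists are synthetic stand-ins, marked `incomplete`, because the source
#' coefficient tables are not redistributed here.
#'
#' @return File path of the YAML registry.
#' @export
radsig_registry_path <- function() {
  system.file("extdata", "registry_hnscc_synthetic.yaml", package = "radsig",
              mustWork = TRUE)
}
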