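# Internal helpers shared across modules.

# Deterministic 32-bit child seed from a master seed, a stage label and an
# index. Keeps every derived seed in [1, 2^31 - 2] and all intermediate
# products well inside the exactly-representable double range.
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stage_num <- sum(utf8ToInt(as.character(stage))) %% 99991
  x <- (abs(master) %% 100003) + 1
  x <- (x * 97003 + stage_num) %% 2147483647
  x <- (x * 30011 + (index %% 65521)) %% 2147483647
  as.integer(x + 1)
}

# Composite key identifying a radiomic feature: the same feature computed on
# a different sequence or image filter is a different feature.
feature_key <- function(modality, image_filter, feature_name) {
  paste(modality, image_filter, feature_name, sep = "|")
}

split_feature_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  tibble(
    modality = vapply(parts, `[`, "", 1L),
    image_filter = vapply(parts, `[`, "", 2L),
    feature_name = vapply(parts, `[`, "", 3L)
  )
}

admitted_modalities <- function() c("T1w", "T1wCont", "T2w")

# Coerce a patients-by-variables table to a numeric matrix with patient ids
# as rownames; first column must be `patient_id`.
table_to_matrix <- function(tbl, what = "table") {
  if (!is.data.frame(tbl) || !"patient_id" %in% names(tbl)) {
    abort(sprintf("%s must be a data frame with a `patient_id` column", what))
  }
  ids <- as.character(tbl$patient_id)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate patient ids in %s", what))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "patient_id")])
  if (!is.numeric(m)) abort(sprintf("%s has non-numeric value columns", what))
  rownames(m) <- ids
  m
}

matrix_to_table <- function(m) {
  out <- as_tibble(m)
  out <- tibble::add_column(out, patient_id = rownames(m), .before = 1L)
  out
}
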