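#' Write a FeatureMatrix as TSV
#'
#' Features as rows, header row of sample ids, empty cell = missing. A JSON
#' sidecar (`<path>.meta.json`) records groups, scale and any processing
#' provenance stored in the object's metadata.
#'
#' @param x a [FeatureMatrix-class]
#' @param path output TSV path.
#' @param sidecar write the JSON sidecar, default TRUE.
#' @return invisibly, `path`.
#' @export
writeFeatureTsv <- function(x, path, sidecar = TRUE) {
  stopifnot(is(x, "FeatureMatrix"))
  v <- intensities(x)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  if (sidecar) {
    meta <- c(list(groups = as.list(groupLabels(x)),
                   scale = scaleFlag(x)),
              S4Vectors::metadata(x)[setdiff(names(S4Vectors::metadata(x)),
                                             "scale")])
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a FeatureMatrix from TSV
#'
#' Expects the dialect of [writeFeatureTsv()]: a `feature_id` column then
#' one column per sample; empty cells are missing. Group labels come from
#' the JSON sidecar when present, else from the `groups` argument.
#'
#' @param path TSV path.
#' @param groups optional character vector of group labels per sample.
#' @param scale declared scale if no sidecar, default `"raw"`.
#' @return a [FeatureMatrix-class]
#' @export
readFeatureTsv <- function(path, groups = NULL, scale = "raw") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(groups)) groups <- unlist(meta$groups)[colnames(v)]
    if (!is.null(meta$scale)) scale <- meta$scale
  }
  if (is.null(groups)) stop("no group labels: supply `groups` or a sidecar")
  FeatureMatrix(v, groups = groups, scale = scale)
}

#' Read a Skyline-style long CSV of targeted peak areas
#'
#' Three columns (`lipid, sample, area`, case-insensitive, any order),
#' pivoted to a raw-scale [FeatureMatrix-class].
#'
#' @param path CSV path.
#' @param groups named character vector: group label per sample id.
#' @return a [FeatureMatrix-class]
#' @export
readSkylineCsv <- function(path, groups) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("lipid", "sample", "area")
  if (!all(need %in% names(df)))
    stop("Skyline CSV needs columns: ", paste(need, collapse = ", "))
  lipids <- unique(df$lipid)
  samples <- unique(df$sample)
  v <- matrix(NA_real_, length(lipids), length(samples),
              dimnames = list(lipids, samples))
  v[cbind(match(df$lipid, lipids), match(df$sample, samples))] <- df$area
  FeatureMatrix(v, groups = groups[samples], scale = "raw")
}

#' Read a MaxQuant-style proteinGroups table subset
#'
#' Tab-separated; columns matched case-insensitively: a protein id column
#' (`Protein IDs` or `protein_id`), `Unique peptides`, `Score`, and
#' per-sample intensity columns identified by `intensityPrefix`.
#'
#' @param path TSV path.
#' @param groups named character vector: group label per sample id (sample
#'   id = intensity column name with the prefix stripped).
#' @param intensityPrefix default `"Intensity "`.
#' @return a [ProteinTable-class] (raw scale; zero intensities read as
#'   missing, the MaxQuant convention).
#' @export
readProteinGroups <- function(path, groups, intensityPrefix = "Intensity ") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  lowerNames <- tolower(names(df))
  findCol <- function(cands) {
    hit <- which(lowerNames %in% tolower(cands))
    if (!length(hit)) stop("missing required column: ", cands[1])
    hit[1]
  }
  idCol <- findCol(c("Protein IDs", "protein_id", "Majority protein IDs"))
  upCol <- findCol(c("Unique peptides", "unique_peptides"))
  scCol <- findCol(c("Score", "score"))
  intCols <- which(startsWith(tolower(names(df)),
                              tolower(intensityPrefix)))
  intCols <- setdiff(intCols, findCol(c("Score", "score"))) # guard overlap
  if (!length(intCols)) stop("no intensity columns with prefix '",
                             intensityPrefix, "'")
  v <- as.matrix(df[, intCols, drop = FALSE])
  colnames(v) <- substring(names(df)[intCols], nchar(intensityPrefix) + 1)
  rownames(v) <- df[[idCol]]
  v[v == 0] <- NA_real_
  ProteinTable(v, groups = groups[colnames(v)],
               unique_peptides = df[[upCol]], score = df[[scCol]],
               scale = "raw")
}

#' Read a GCT v1.2 expression matrix
#'
#' Header line `#1.2`, a dimensions line, then a table with `Name` and
#' `Description` columns followed by one column per sample.
#'
#' @param path GCT path.
#' @param groups optional named character vector: group per sample id;
#'   samples without a label are dropped if `groups` is given.
#' @return a [FeatureMatrix-class] on the log2 scale (the distribution
#'   convention of public expression matrices; no transformation applied).
#' @export
readGct <- function(path, groups = NULL) {
  lines <- readLines(path, n = 2, warn = FALSE)
  if (!grepl("^#1\\.2", lines[1])) stop("not a GCT v1.2 file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]][1:2])
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) != dims[1])
    stop(sprintf("GCT declares %d rows but has %d", dims[1], nrow(df)))
  v <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(v) <- df[[1]]
  if (!is.null(groups)) {
    keep <- colnames(v) %in% names(groups)
    v <- v[, keep, drop = FALSE]
    grp <- groups[colnames(v)]
  } else {
    grp <- rep("all", ncol(v))
  }
  fm <- FeatureMatrix(v, groups = grp, scale = "log2")
  S4Vectors::metadata(fm)$description <- setNames(df[[2]], df[[1]])
  fm
}

#' Write a GCT v1.2 expression matrix
#'
#' @param x a [FeatureMatrix-class]
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGct <- function(x, path) {
  v <- intensities(x)
  desc <- S4Vectors::metadata(x)$description
  if (is.null(desc)) desc <- setNames(rownames(v), rownames(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
  df <- data.frame(Name = rownames(v),
                   Description = unname(desc[rownames(v)]),
                   v, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column TSV id mapping
#'
#' @param path TSV with header `source_id<TAB>target_id` (or any two
#'   columns, taken in order).
#' @return data.frame with `source_id`, `target_id`.
#' @export
readIdMapping <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("id mapping needs two columns")
  out <- data.frame(source_id = as.character(df[[1]]),
                    target_id = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$target_id)) || anyNA(out$target_id))
    stop("id mapping contains empty target ids")
  out
}

#' Write differential results as TSV
#'
#' Columns `feature_id, logFC, t, p_value, adj_p_value, significant_raw,
#' significant_adj, direction`.
#'
#' @param results output of [callSignificant()] / [runDifferential()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDifferentialTsv <- function(results, path) {
  cols <- c("feature_id", "logFC", "t", "p_value", "adj_p_value",
            "significant_raw", "significant_adj", "direction")
  utils::write.table(results[, intersect(cols, names(results))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
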