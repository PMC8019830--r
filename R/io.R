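## Plain-text readers and writers for phenotypes, genotypes, Q matrices
## and solutions.

#' Read a phenotype table
#'
#' CSV with an `animal` column, fixed-effect columns and trait columns;
#' `NA` is the missing-value token.
#'
#' @param path CSV file path.
#' @return data.frame with `animal` as character.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (!"animal" %in% names(df))
    stop("phenotype file needs an 'animal' column")
  df$animal <- as.character(df$animal)
  df
}

#' Read a genotype table
#'
#' Whitespace- or comma-separated; first column the animal original id,
#' remaining columns marker codes, with a header row of marker ids.
#' Dosage coding 0/1/2 is detected (no negative codes) and re-centered
#' to -1/0/+1.
#'
#' @param path file path.
#' @param ped sorted [Pedigree-class] used to map original to internal
#'   ids.
#' @param strict reject missing genotypes instead of mean-imputing.
#' @return a [GenotypeMatrix-class] with rows ascending by internal id.
#' @export
readGenotypes <- function(path, ped, strict = FALSE) {
  sep <- if (grepl(",", readLines(path, n = 1))) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, strip.white = TRUE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[-1])
  idx <- match(ids, ped@id)
  if (anyNA(idx))
    stop("genotyped animals absent from the pedigree: ",
         paste(ids[is.na(idx)], collapse = ", "))
  ord <- order(idx)
  coding <- if (min(M, na.rm = TRUE) < 0) "centered" else "dosage"
  genotypeMatrix(M[ord, , drop = FALSE], markerIds = colnames(M),
                 animalIds = idx[ord], coding = coding, strict = strict)
}

#' Write a genotype table
#' @param g a [GenotypeMatrix-class].
#' @param ped sorted [Pedigree-class] (for original ids).
#' @param path output path (whitespace-separated, -1/0/+1 codes).
#' @return the path, invisibly.
#' @export
writeGenotypes <- function(g, ped, path) {
  df <- data.frame(animal = ped@id[g@animalIds], g@M,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("animal", g@markerIds)
  utils::write.table(df, path, sep = " ", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a Q (group fraction) matrix
#'
#' CSV with an `animal` column and one column per group.
#'
#' @param path file path.
#' @param ped sorted [Pedigree-class]; rows are reordered to internal
#'   id order and must cover every animal.
#' @return a [GroupMap-class].
#' @export
readQMatrix <- function(path, ped) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (!"animal" %in% names(df)) stop("Q file needs an 'animal' column")
  idx <- match(ped@id, as.character(df$animal))
  if (anyNA(idx))
    stop("Q file must cover every pedigree animal")
  Q <- as.matrix(df[idx, setdiff(names(df), "animal"), drop = FALSE])
  rownames(Q) <- ped@id
  new("GroupMap", groupIds = colnames(Q), Q = Q)
}

#' Write labeled solutions as TSV
#'
#' Columns: `effect`, `level` (factor level / animal original id /
#' group id), `trait`, `value`.
#'
#' @param sol a [Solutions-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSolutions <- function(sol, path) {
  utils::write.table(as.data.frame(sol), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pedigree as CSV
#' @param ped a [Pedigree-class].
#' @param path output path (`animal,sire,dam[,group]` with original ids).
#' @return the path, invisibly.
#' @export
writePedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  keep <- c("animal", "sire", "dam")
  if (any(nzchar(df$group))) keep <- c(keep, "group")
  utils::write.csv(df[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
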