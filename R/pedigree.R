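#' Read a pedigree file
#'
#' Reads a 3-column CSV `id,sire,dam` (header required, UTF-8). An empty
#' field marks an unknown parent; a founder is any individual with both
#' parents unknown.
#'
#' @param path Path to the CSV file.
#' @return A data frame with character columns `id`, `sire`, `dam` (`NA` =
#'   unknown parent).
#' @seealso [topo_sort_pedigree()], [build_A()]
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = c("", "NA", "0"),
                        fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns id, sire, dam (line 1)")
  }
  ped <- df[, need]
  dup <- duplicated(ped$id)
  if (any(dup)) {
    stop("duplicate pedigree id '", ped$id[which(dup)[1]], "' (line ",
         which(dup)[1] + 1L, ")")
  }
  ped
}

#' Write a pedigree table to CSV
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`).
#' @param path Output path; unknown parents are written as empty fields.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("id", "sire", "dam")]
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Topologically sort a pedigree
#'
#' Orders records so that every parent precedes its offspring, preserving the
#' input order among individuals at the same depth (stable sort). Required
#' before [build_A()].
#'
#' @param ped Data frame with columns `id`, `sire`, `dam`; `NA` = unknown.
#' @param add_founders If `TRUE`, parent ids that never appear as records are
#'   inserted as founder rows; if `FALSE` (default) such ids raise an error.
#' @return The sorted pedigree data frame.
#' @export
topo_sort_pedigree <- function(ped, add_founders = FALSE) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)

  parents <- setdiff(stats::na.omit(unique(c(ped$sire, ped$dam))), ped$id)
  if (length(parents) > 0) {
    if (!add_founders) {
      stop("parent id '", parents[1],
           "' never defined; set add_founders = TRUE to insert as founder")
    }
    ped <- rbind(data.frame(id = parents, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped[, c("id", "sire", "dam")])
  }

  n <- nrow(ped)
  s <- match(ped$sire, ped$id)  # NA for unknown parent
  d <- match(ped$dam, ped$id)
  # iterative depth assignment; a full pass with no progress means a cycle
  depth <- rep(NA_integer_, n)
  depth[is.na(s) & is.na(d)] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (length(todo) == 0) break
    ds <- ifelse(is.na(s[todo]), -1L, depth[s[todo]])
    dd <- ifelse(is.na(d[todo]), -1L, depth[d[todo]])
    ready <- !is.na(ds) & !is.na(dd)
    if (!any(ready)) {
      stop("pedigree cycle detected involving individual '", ped$id[todo[1]], "'")
    }
    depth[todo[ready]] <- pmax(ds[ready], dd[ready]) + 1L
  }
  out <- ped[order(depth, seq_len(n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_topo_sorted <- function(ped) {
  pos_s <- match(ped$sire, ped$id)
  pos_d <- match(ped$dam, ped$id)
  i <- seq_len(nrow(ped))
  all(is.na(pos_s) | pos_s < i) && all(is.na(pos_d) | pos_d < i)
}

#' Build the numerator relationship matrix A
#'
#' Computes Wright/Henderson additive relationships by the tabular method:
#' for individual i with parents s, d (processed parents-first),
#' `a(i,i) = 1 + 0.5 * a(s,d)` and `a(i,j) = 0.5 * (a(j,s) + a(j,d))` for
#' earlier j, with terms involving an unknown parent set to 0. Inbreeding is
#' accumulated on the diagonal (1 + F); founders have `a(i,i) = 1`.
#'
#' @param ped Topologically sorted pedigree (see [topo_sort_pedigree()]).
#' @return A [kernel] named `"A"` over the pedigree ids.
#' @export
build_A <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  if (!is_topo_sorted(ped)) {
    stop("pedigree is not sorted parents-first; call topo_sort_pedigree() first")
  }
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + A[j, si]
      if (!is.na(di)) row <- row + A[j, di]
      row <- 0.5 * row
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- if (!is.na(si) && !is.na(di)) 1 + 0.5 * A[si, di] else 1
  }
  kernel(A, name = "A")
}
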