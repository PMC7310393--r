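#' Coerce a data frame to a validated pedigree
#'
#' Builds a topologically sorted pedigree from animal/sire/dam triples.
#' Parents that are referenced but not listed as animals are added as
#' founders ("completion"). Unknown parents may be encoded as `NA`, an
#' empty string, or `"0"`; all are normalized to `NA`.
#'
#' @param x A data frame with columns `animal`, `sire`, `dam`, and
#'   optionally `birth_year` and `origin_country`.
#' @return A tibble of class `pedigree`, one row per animal, sorted so that
#'   every parent precedes all of its offspring. Columns `sire_idx` and
#'   `dam_idx` hold the 1-based row indices of the parents (`NA` if
#'   unknown); the row number is the animal's dense index.
#' @details Duplicated animal identifiers and pedigree cycles (an animal
#'   being its own ancestor) abort with an error listing the offending
#'   animals; the analysis contract is strict and invalid animals must be
#'   removed upstream.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   animal = c("o", "s", "d"), sire = c("s", NA, NA), dam = c("d", NA, NA)
#' ))
#' ped$animal # parents first
#' @export
as_pedigree <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(x))) {
    abort(paste0("pedigree needs columns ", paste(need, collapse = ", ")))
  }
  norm <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & (v == "" | v == "0")] <- NA_character_
    v
  }
  animal <- as.character(x$animal)
  if (anyNA(animal) || any(animal == "" | animal == "0")) {
    abort("animal identifiers must be non-missing and not '0'")
  }
  dup <- unique(animal[duplicated(animal)])
  if (length(dup) > 0) {
    abort(paste0("duplicated animal identifiers: ",
                 paste(head(dup, 10), collapse = ", ")))
  }
  sire <- norm(x$sire)
  dam <- norm(x$dam)
  birth_year <- if ("birth_year" %in% names(x)) as.integer(x$birth_year) else
    rep(NA_integer_, length(animal))
  origin <- if ("origin_country" %in% names(x)) norm(x$origin_country) else
    rep(NA_character_, length(animal))

  # completion: referenced parents absent from the animal column -> founders
  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  missing_par <- setdiff(parents, animal)
  if (length(missing_par) > 0) {
    animal <- c(animal, missing_par)
    sire <- c(sire, rep(NA_character_, length(missing_par)))
    dam <- c(dam, rep(NA_character_, length(missing_par)))
    birth_year <- c(birth_year, rep(NA_integer_, length(missing_par)))
    origin <- c(origin, rep(NA_character_, length(missing_par)))
  }

  n <- length(animal)
  idx <- setNames(seq_len(n), animal)
  s_i <- unname(idx[sire])
  d_i <- unname(idx[dam])

  # Kahn topological sort, ties broken by input order (FIFO)
  indeg <- (!is.na(s_i)) + (!is.na(d_i))
  kids <- vector("list", n)
  par_edges <- c(s_i, d_i)
  child_edges <- c(seq_len(n), seq_len(n))
  keep <- !is.na(par_edges)
  if (any(keep)) {
    kids_split <- split(child_edges[keep], par_edges[keep])
    kids[as.integer(names(kids_split))] <- kids_split
  }
  queue <- which(indeg == 0L)
  order_out <- integer(n)
  qhead <- 1L
  placed <- 0L
  queue <- as.integer(queue)
  while (qhead <= length(queue)) {
    v <- queue[qhead]; qhead <- qhead + 1L
    placed <- placed + 1L
    order_out[placed] <- v
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (placed < n) {
    bad <- which(indeg > 0L)
    # walk parent links from one offending animal until a repeat: one cycle
    path <- integer(0)
    v <- bad[1]
    while (!(v %in% path)) {
      path <- c(path, v)
      p <- c(s_i[v], d_i[v])
      p <- p[!is.na(p) & p %in% bad]
      v <- p[1]
    }
    cyc <- animal[c(path[which(path == v)[1]:length(path)], v)]
    abort(paste0("pedigree cycle detected: ", paste(cyc, collapse = " -> ")))
  }

  ord <- order_out
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  out <- tibble(
    animal = animal[ord],
    sire = sire[ord],
    dam = dam[ord],
    birth_year = birth_year[ord],
    origin_country = origin[ord],
    sire_idx = ifelse(is.na(s_i[ord]), NA_integer_, pos[s_i[ord]]),
    dam_idx = ifelse(is.na(d_i[ord]), NA_integer_, pos[d_i[ord]])
  )
  class(out) <- c("pedigree", class(out))
  out
}

#' Read a pedigree CSV file
#'
#' @param path Path to a CSV file with header columns
#'   `animal,sire,dam,birth_year,origin_country`.
#' @return A [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("animal", "sire", "dam", "birth_year", "origin_country")
  if (!all(need %in% names(df))) {
    abort(paste0("pedigree file must have header columns ",
                 paste(need, collapse = ",")))
  }
  as_pedigree(df)
}

#' Restrict a pedigree to a set of animals and all their ancestors
#'
#' Mirrors "prediction" pruning in pedigree software: the returned pedigree
#' contains exactly `keep_ids` plus every ancestor, with no generation
#' limit, order preserved.
#'
#' @param ped A `pedigree`.
#' @param keep_ids Character vector of animal identifiers to keep.
#' @return A pruned `pedigree`.
#' @export
prune_pedigree <- function(ped, keep_ids) {
  stopifnot(inherits(ped, "pedigree"))
  keep_ids <- unique(as.character(keep_ids))
  unknown <- setdiff(keep_ids, ped$animal)
  if (length(unknown) > 0) {
    abort(paste0("unknown animals in keep_ids: ",
                 paste(head(unknown, 10), collapse = ", ")))
  }
  n <- nrow(ped)
  keep <- logical(n)
  keep[match(keep_ids, ped$animal)] <- TRUE
  if (n > 0) {
    for (i in n:1) {
      if (keep[i]) {
        if (!is.na(ped$sire_idx[i])) keep[ped$sire_idx[i]] <- TRUE
        if (!is.na(ped$dam_idx[i])) keep[ped$dam_idx[i]] <- TRUE
      }
    }
  }
  out <- ped[keep, c("animal", "sire", "dam", "birth_year", "origin_country")]
  as_pedigree(out)
}

#' Maximum generation depth of a pedigree
#'
#' Founders have depth 0; an animal's depth is one more than the deeper of
#' its parents. Returns the maximum over all animals (the longest
#' founder-to-animal path).
#'
#' @param ped A `pedigree`.
#' @return Integer depth (0 for a founders-only or empty pedigree).
#' @export
max_generation_depth <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (n == 0) return(0L)
  depth <- integer(n)
  for (i in seq_len(n)) {
    ds <- if (is.na(ped$sire_idx[i])) -1L else depth[ped$sire_idx[i]]
    dd <- if (is.na(ped$dam_idx[i])) -1L else depth[ped$dam_idx[i]]
    depth[i] <- max(ds, dd) + 1L
  }
  max(depth)
}

# internal: Meuwissen-Luo inbreeding F and Mendelian sampling fractions d
.ped_inbreeding <- function(ped, use_inbreeding = TRUE) {
  s <- ifelse(is.na(ped$sire_idx), 0L, ped$sire_idx)
  d <- ifelse(is.na(ped$dam_idx), 0L, ped$dam_idx)
  res <- inbreeding_ml_cpp(s, d)
  if (!use_inbreeding) {
    res$F <- rep(0, nrow(ped))
    res$d <- ifelse(s > 0 & d > 0, 0.5, ifelse(s > 0 | d > 0, 0.75, 1))
  }
  res
}

#' Inbreeding coefficients
#'
#' Computes per-animal inbreeding coefficients F (the diagonal of the
#' numerator relationship matrix minus one) by the Meuwissen-Luo
#' algorithm.
#'
#' @param ped A `pedigree`.
#' @return A tibble with columns `animal` and `inbreeding`.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  tibble(animal = ped$animal, inbreeding = .ped_inbreeding(ped)$F)
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Intended for small pedigrees (reference computations and teaching); the
#' mixed-model machinery only ever uses the sparse inverse from
#' [a_inverse()].
#'
#' @param ped A `pedigree`.
#' @return A dense symmetric matrix with animal identifiers as dimnames.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (is.na(s)) 0 else A[s, j]
      ad_ <- if (is.na(d)) 0 else A[d, j]
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from per-animal contributions (Henderson's
#' rules), with Mendelian sampling variances adjusted for parental
#' inbreeding by default.
#'
#' @param ped A `pedigree`.
#' @param use_inbreeding If `FALSE`, parental inbreeding is ignored in the
#'   Mendelian sampling variances (faster on toy data, inexact when the
#'   pedigree is inbred).
#' @return An object of class `relationship_inverse`: a list with the
#'   sparse symmetric `matrix`, the per-animal `inbreeding` coefficients,
#'   and the animal `ids`.
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  inb <- .ped_inbreeding(ped, use_inbreeding)
  alpha <- 1 / inb$d
  s <- ped$sire_idx
  d <- ped$dam_idx
  i_all <- seq_len(n)

  ii <- list(i_all); jj <- list(i_all); xx <- list(alpha)
  hs <- !is.na(s); hd <- !is.na(d); hb <- hs & hd
  if (any(hs)) {
    ii <- c(ii, list(i_all[hs], s[hs], s[hs]))
    jj <- c(jj, list(s[hs], i_all[hs], s[hs]))
    xx <- c(xx, list(-alpha[hs] / 2, -alpha[hs] / 2, alpha[hs] / 4))
  }
  if (any(hd)) {
    ii <- c(ii, list(i_all[hd], d[hd], d[hd]))
    jj <- c(jj, list(d[hd], i_all[hd], d[hd]))
    xx <- c(xx, list(-alpha[hd] / 2, -alpha[hd] / 2, alpha[hd] / 4))
  }
  if (any(hb)) {
    ii <- c(ii, list(s[hb], d[hb]))
    jj <- c(jj, list(d[hb], s[hb]))
    xx <- c(xx, list(alpha[hb] / 4, alpha[hb] / 4))
  }
  m <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, n), dimnames = list(ped$animal, ped$animal)
  )
  structure(
    list(matrix = m, inbreeding = inb$F, mendelian_d = inb$d, ids = ped$animal),
    class = "relationship_inverse"
  )
}

#' @export
print.relationship_inverse <- function(x, ...) {
  cat("Inverse numerator relationship matrix:", length(x$ids), "animals,",
      Matrix::nnzero(x$matrix), "non-zeros; mean F =",
      signif(mean(x$inbreeding), 4), "\n")
  invisible(x)
}

#' Write a relationship inverse as coordinate-format text
#'
#' Writes the lower triangle as `i,j,value` with 1-based indices.
#'
#' @param x A `relationship_inverse`.
#' @param path Output file path.
#' @export
write_a_inverse <- function(x, path) {
  stopifnot(inherits(x, "relationship_inverse"))
  tm <- as(as(x$matrix, "TsparseMatrix"), "generalMatrix")
  keep <- tm@i >= tm@j
  df <- tibble(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L, value = tm@x[keep]) %>%
    arrange(.data$i, .data$j)
  readr::write_csv(df, path)
  invisible(path)
}
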