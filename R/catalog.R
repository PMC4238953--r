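#' Reaction catalogs
#'
#' A reaction catalog maps opaque reaction identifiers to their substrate and
#' product compound sets and precomputes, for every reaction, the list of
#' directed substrate--product pairs the model operates on. Compounds are
#' indexed densely in first-appearance order; all file formats use the string
#' identifiers so the internal indexing never leaks.
#'
#' Two pair decompositions are supported. `"cartesian"` (the default, and the
#' natural reading for curated reaction definitions) forms every pair in
#' substrate-set x product-set, so a reaction with a substrates and b products
#' contributes J = a*b pairs. `"zip"` pairs the i-th listed substrate with the
#' i-th listed product (requiring equal list lengths) and is the decomposition
#' under which simulator-written catalogs round-trip exactly, because the
#' generative process draws one substrate and one product per pair.
#'
#' @param compound_ids Character vector of distinct compound identifiers.
#' @param reaction_ids Character vector of distinct reaction identifiers.
#' @param substrates,products Lists (one element per reaction) of integer
#'   compound indices into `compound_ids`.
#' @param pairing `"cartesian"` or `"zip"` (see Details).
#' @param reversible Logical vector, one flag per reaction; a reversible
#'   reaction also contributes every pair in the product-to-substrate
#'   direction.
#' @return An object of class `reaction_catalog` with components
#'   `compound_ids`, `reaction_ids`, `substrates`, `products`, `sub_slots`,
#'   `prod_slots` (per-reaction compound index of each pair's substrate and
#'   product slot) and `J` (pairs per reaction).
#' @export
reaction_catalog <- function(compound_ids, reaction_ids, substrates, products,
                             pairing = c("cartesian", "zip"),
                             reversible = NULL) {
  pairing <- match.arg(pairing)
  compound_ids <- as.character(compound_ids)
  reaction_ids <- as.character(reaction_ids)
  if (anyDuplicated(compound_ids)) stop_usage("duplicate compound identifiers")
  if (anyDuplicated(reaction_ids)) stop_usage("duplicate reaction identifiers")
  R <- length(reaction_ids)
  if (length(substrates) != R || length(products) != R) {
    stop_usage("substrates/products must have one entry per reaction")
  }
  if (is.null(reversible)) reversible <- rep(FALSE, R)
  C <- length(compound_ids)
  sub_slots <- vector("list", R)
  prod_slots <- vector("list", R)
  for (r in seq_len(R)) {
    s <- as.integer(substrates[[r]])
    p <- as.integer(products[[r]])
    if (length(s) == 0L || length(p) == 0L) {
      stop_usage(sprintf("reaction '%s' has an empty substrate or product list",
                         reaction_ids[[r]]))
    }
    if (any(s < 1L | s > C) || any(p < 1L | p > C)) {
      stop_reference(sprintf("reaction '%s' references an unknown compound index",
                             reaction_ids[[r]]))
    }
    if (pairing == "cartesian") {
      s <- unique(s); p <- unique(p)
      substrates[[r]] <- s
      products[[r]] <- p
      ss <- rep(s, each = length(p))
      pp <- rep(p, times = length(s))
    } else {
      if (length(s) != length(p)) {
        stop_usage(sprintf(
          "zip pairing requires equally many substrates and products (reaction '%s')",
          reaction_ids[[r]]))
      }
      substrates[[r]] <- s
      products[[r]] <- p
      ss <- s
      pp <- p
    }
    if (isTRUE(reversible[[r]])) {
      tmp <- ss
      ss <- c(ss, pp)
      pp <- c(pp, tmp)
    }
    sub_slots[[r]] <- ss
    prod_slots[[r]] <- pp
  }
  structure(
    list(compound_ids = compound_ids,
         reaction_ids = reaction_ids,
         substrates = substrates,
         products = products,
         sub_slots = sub_slots,
         prod_slots = prod_slots,
         J = lengths(sub_slots),
         pairing = pairing,
         reversible = as.logical(reversible)),
    class = "reaction_catalog")
}

#' @export
print.reaction_catalog <- function(x, ...) {
  cat(sprintf("<reaction_catalog> %d reactions, %d compounds, %d pairs (%s pairing)\n",
              length(x$reaction_ids), length(x$compound_ids), sum(x$J), x$pairing))
  invisible(x)
}

n_compounds <- function(catalog) length(catalog$compound_ids)
n_reactions <- function(catalog) length(catalog$reaction_ids)

#' Read a reaction catalog from a tab-separated file
#'
#' Expected columns: `reaction_id`, comma-joined substrate compound IDs,
#' comma-joined product compound IDs, and an optional fourth `0`/`1`
#' reversibility flag. Lines starting with `#` are comments. Compound indices
#' are assigned in first-appearance order.
#'
#' @param path Path to the file.
#' @param exclude Optional character vector of compound IDs (e.g. currency
#'   compounds such as ATP or water) removed from every reaction before pair
#'   decomposition. Reactions left with no substrates or no products are
#'   dropped with a warning.
#' @inheritParams reaction_catalog
#' @return A [reaction_catalog()].
#' @export
read_catalog <- function(path, exclude = NULL,
                         pairing = c("cartesian", "zip")) {
  pairing <- match.arg(pairing)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_format(sprintf("no reactions in '%s'", path))

  rid <- character(0)
  subs_ids <- list()
  prods_ids <- list()
  rever <- logical(0)
  dropped <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (!(length(f) %in% c(3L, 4L)) || !nzchar(f[[1]])) {
      stop_format(sprintf("%s line %d: expected 3 or 4 tab-separated fields",
                          path, lineno[[i]]))
    }
    s <- strsplit(f[[2]], ",", fixed = TRUE)[[1]]
    p <- strsplit(f[[3]], ",", fixed = TRUE)[[1]]
    s <- s[nzchar(s)]; p <- p[nzchar(p)]
    if (!is.null(exclude)) {
      s <- setdiff2(s, exclude); p <- setdiff2(p, exclude)
      if (length(s) == 0L || length(p) == 0L) {
        dropped <- c(dropped, f[[1]])
        next
      }
    }
    if (length(s) == 0L || length(p) == 0L) {
      stop_format(sprintf("%s line %d: empty substrate or product list",
                          path, lineno[[i]]))
    }
    rv <- FALSE
    if (length(f) == 4L) {
      if (!f[[4]] %in% c("0", "1")) {
        stop_format(sprintf("%s line %d: reversible flag must be 0 or 1",
                            path, lineno[[i]]))
      }
      rv <- f[[4]] == "1"
    }
    if (f[[1]] %in% rid) {
      stop_format(sprintf("%s line %d: duplicate reaction_id '%s'",
                          path, lineno[[i]], f[[1]]))
    }
    rid <- c(rid, f[[1]])
    subs_ids <- c(subs_ids, list(s))
    prods_ids <- c(prods_ids, list(p))
    rever <- c(rever, rv)
  }
  if (length(dropped) > 0L) {
    warning(sprintf("dropped %d reaction(s) emptied by the exclusion list: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(rid) == 0L) stop_format(sprintf("no reactions left in '%s'", path))

  compound_ids <- unique(unlist(mapply(c, subs_ids, prods_ids,
                                       SIMPLIFY = FALSE), use.names = FALSE))
  idx <- stats::setNames(seq_along(compound_ids), compound_ids)
  reaction_catalog(
    compound_ids = compound_ids,
    reaction_ids = rid,
    substrates = lapply(subs_ids, function(s) unname(idx[s])),
    products = lapply(prods_ids, function(p) unname(idx[p])),
    pairing = pairing,
    reversible = rever)
}

# setdiff preserving order and multiplicity of x
setdiff2 <- function(x, y) x[!(x %in% y)]

#' Write a reaction catalog to a tab-separated file
#'
#' Inverse of [read_catalog()] (given the same `pairing`): reaction IDs,
#' substrate sets and product sets round-trip exactly.
#'
#' @param catalog A [reaction_catalog()].
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "reaction_catalog"))
  sub <- vapply(catalog$substrates,
                function(s) paste(catalog$compound_ids[s], collapse = ","), "")
  prod <- vapply(catalog$products,
                 function(p) paste(catalog$compound_ids[p], collapse = ","), "")
  lines <- paste(catalog$reaction_ids, sub, prod, sep = "\t")
  if (any(catalog$reversible)) {
    lines <- paste(lines, as.integer(catalog$reversible), sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}
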