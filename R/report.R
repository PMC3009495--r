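# ---- tab-delimited interaction tables ----------------------------------

.provenance_lines <- function(x) {
  w <- attr(x, "window")
  c(sprintf("# input: %s", attr(attr(x, "sites"), "structure_id")),
    sprintf("# atom_type: %s", attr(attr(x, "sites"), "atom_type")),
    sprintf("# window: [%.2f, %.2f]", w[1], w[2]),
    sprintf("# min_seq_sep: %d", attr(x, "min_seq_sep")),
    sprintf("# n_sites: %d", nrow(attr(x, "sites"))))
}

#' Write interactions to a tab-delimited file
#'
#' One row per interaction: order, member descriptors
#' (\code{CHAIN:RESNAME:RESNUM[:ICODE]}), all pairwise distances (2
#' decimal places by default), span label. Provenance (input id, atom
#' type, window, minimum sequence separation) is written as
#' \code{#}-prefixed header lines. Output is byte-stable across runs.
#'
#' A single \code{"interaction_set"} or a list of sets (mixed orders) is
#' accepted; with mixed orders, member and distance columns are padded
#' with empty fields up to order 4.
#'
#' @param x an \code{"interaction_set"} or list of them.
#' @param file destination path.
#' @param precision decimal places for distances (default 2).
#' @return \code{file}, invisibly.
#' @export
write_interactions_tsv <- function(x, file, precision = 2) {
  sets <- if (inherits(x, "interaction_set")) list(x) else x
  stopifnot(all(vapply(sets, inherits, logical(1), "interaction_set")))
  kmax <- max(vapply(sets, function(s) attr(s, "order"), integer(1)))
  mcols <- paste0("member", seq_len(kmax))
  dcols <- .pair_labels(kmax)
  header <- c("order", mcols, dcols, "span")
  rows <- character(0)
  for (s in sets) {
    fi <- format_interactions(s, digits = precision)
    for (cc in c(mcols, dcols)) if (is.null(fi[[cc]])) fi[[cc]] <- ""
    fi <- fi[, header, drop = FALSE]
    if (nrow(fi) > 0)
      rows <- c(rows, apply(fi, 1, paste, collapse = "\t"))
  }
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(c(.provenance_lines(sets[[1]]),
               paste(header, collapse = "\t"), rows),
             con, useBytes = TRUE)
  invisible(file)
}

#' Read back a tab-delimited interaction table
#'
#' Inverse of \code{\link{write_interactions_tsv}} at reporting precision:
#' reconstructs order, member descriptors, distances and span.
#'
#' @param file path to a file written by \code{write_interactions_tsv}.
#' @return data.frame with the table's columns; provenance lines are
#'   returned in attribute \code{"provenance"}.
#' @export
read_interactions_tsv <- function(file) {
  lines <- readLines(file, warn = FALSE)
  prov <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) stop("no header row in ", file)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  df$order <- as.integer(df$order)
  for (cc in grep("^d[0-9]{2}$", names(df), value = TRUE))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  attr(df, "provenance") <- prov
  df
}

# ---- visualization scripts ---------------------------------------------

.viz_colors <- c("2" = "blue", "3" = "green", "4" = "red")

# residue selection tokens (RESNO:CHAIN) for one interaction row
.row_tokens <- function(sites, idx) {
  paste0(sites$resno[idx], ifelse(sites$insert[idx] == "", "",
                                  paste0("^", sites$insert[idx])),
         ":", sites$chain[idx])
}

#' Write a RasMol or Jmol selection script for interactions
#'
#' Emits one selection + colour command per interaction so member residues
#' can be highlighted on the query structure; each interaction order gets
#' a distinct colour (pairs blue, triplets green, quadruplets red). Both
#' dialects select identical residue sets.
#'
#' @param x an \code{"interaction_set"} or list of them (mixed orders).
#' @param dialect \code{"rasmol"} or \code{"jmol"}.
#' @param file destination path.
#' @return \code{file}, invisibly.
#' @export
write_viz_script <- function(x, dialect = c("rasmol", "jmol"), file) {
  dialect <- match.arg(dialect)
  sets <- if (inherits(x, "interaction_set")) list(x) else x
  stopifnot(all(vapply(sets, inherits, logical(1), "interaction_set")))
  total <- sum(vapply(sets, nrow, integer(1)))
  if (total == 0) stop("no interactions to visualize")
  lines <- if (dialect == "jmol")
    c("# residue selections for higher-order interactions",
      "select all; wireframe off; backbone 50;")
  else
    c("# residue selections for higher-order interactions",
      "wireframe off", "backbone 50")
  for (s in sets) {
    k <- attr(s, "order")
    sites <- attr(s, "sites")
    col <- .viz_colors[[as.character(k)]]
    m <- .members(s)
    for (r in seq_len(nrow(m))) {
      toks <- .row_tokens(sites, m[r, ])
      sel <- paste(toks, collapse = ", ")
      lines <- c(lines, if (dialect == "jmol")
        sprintf("select %s; color %s; spacefill 120;", sel, col)
      else
        c(sprintf("select %s", sel), sprintf("color %s", col),
          "spacefill 120"))
    }
  }
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(file)
}

# ---- summaries ----------------------------------------------------------

#' Summarize interaction sets
#'
#' Counts interactions per order and span, and tallies per-residue
#' participation (how many interactions of each order each residue
#' joins). The participation counts satisfy
#' \code{sum(participation at order k) == k * count(order k)}.
#'
#' @param x an \code{"interaction_set"} or list of them.
#' @param sites the site table the interactions were computed from
#'   (defaults to the table attached to the first set).
#' @return object of class \code{"interaction_summary"}: list with
#'   \code{counts} (data.frame order, n, intra_chain, inter_chain) and
#'   \code{participation} (data.frame residue key, resid, one count
#'   column per order).
#' @export
summarize_interactions <- function(x, sites = NULL) {
  sets <- if (inherits(x, "interaction_set")) list(x) else x
  stopifnot(all(vapply(sets, inherits, logical(1), "interaction_set")))
  if (is.null(sites)) sites <- attr(sets[[1]], "sites")
  keys <- site_key(sites$chain, sites$resno, sites$insert)
  part <- data.frame(residue = keys, resid = sites$resid,
                     stringsAsFactors = FALSE)
  counts <- data.frame(order = integer(0), n = integer(0),
                       intra_chain = integer(0), inter_chain = integer(0))
  for (s in sets) {
    k <- attr(s, "order")
    m <- .members(s)
    counts <- rbind(counts, data.frame(
      order = k, n = nrow(m),
      intra_chain = sum(s$span == "intra-chain"),
      inter_chain = sum(s$span == "inter-chain")))
    tab <- tabulate(as.vector(m), nbins = nrow(sites))
    part[[paste0("order", k)]] <- tab
  }
  counts <- counts[order(counts$order), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts, participation = part),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat("Interaction counts:\n")
  print(x$counts, row.names = FALSE)
  oc <- grep("^order", names(x$participation), value = TRUE)
  if (length(oc) > 0) {
    busy <- x$participation[order(-rowSums(x$participation[, oc, drop = FALSE])), ]
    cat("\nMost connected residues:\n")
    print(utils::head(busy, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Write an interaction summary as TSV
#'
#' @param x an \code{"interaction_summary"}.
#' @param file destination path.
#' @return \code{file}, invisibly.
#' @export
write_summary_tsv <- function(x, file) {
  stopifnot(inherits(x, "interaction_summary"))
  con <- file(file, open = "wb")
  on.exit(close(con))
  fmt <- function(df) c(paste(names(df), collapse = "\t"),
                        apply(df, 1, function(r) paste(trimws(r), collapse = "\t")))
  writeLines(c("# interaction counts", fmt(x$counts), "",
               "# per-residue participation", fmt(x$participation)),
             con, useBytes = TRUE)
  invisible(file)
}
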