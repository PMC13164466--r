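#' @title SMILES attribute extraction
#' @description Functions that turn a SMILES string into the three attribute
#'   families used by the correlation-weight descriptor: single SMILES-atoms
#'   (S_k), connected SMILES-atom pairs (SS_k), and per-vertex Nearest
#'   Neighbor Codes (NNC) computed on the hydrogen-suppressed molecular graph.
#' @name featurize
NULL

# Two-letter organic-subset elements recognised outside brackets.
.two_letter <- c("Cl", "Br")

# Single-letter atom tokens recognised outside brackets (aromatic lowercase
# included; 'l' and 'r' never start an atom).
.atom_letters <- c("B", "C", "N", "O", "P", "S", "F", "I",
                   "b", "c", "n", "o", "p", "s")

.bond_chars <- c("=", "#", "-", "/", "\\", ":")

#' Tokenize a SMILES string into SMILES-atoms
#'
#' Splits a SMILES string into its smallest separately examinable units:
#' bracket atoms `[...]` are single tokens, the two-letter organic-subset
#' elements `Cl` and `Br` are single tokens, and every other character
#' (ring-closure digits, bond symbols, branch parentheses, charges, stereo
#' slashes) is its own token. Concatenating the tokens reproduces the input
#' exactly.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of tokens whose concatenation equals `smiles`.
#' @examples
#' tokenize("C=O")       # "C" "=" "O"
#' tokenize("OCC1CC1Cl") # ring digits and Cl kept intact
#' @export
tokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("malformed SMILES: input must be a single character string")
  }
  if (nchar(smiles) == 0L) {
    stop("malformed SMILES: empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  if (any(utf8ToInt(smiles) > 127L)) {
    stop("malformed SMILES: non-ASCII character at position ",
         which(utf8ToInt(smiles) > 127L)[1L])
  }
  n <- length(chars)
  tokens <- character(0L)
  depth <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") {
        if (chars[j] == "[") {
          stop("malformed SMILES: nested '[' at position ", j)
        }
        j <- j + 1L
      }
      if (j > n) stop("malformed SMILES: unbalanced '[' at position ", i)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop("malformed SMILES: unbalanced ']' at position ", i)
    } else if (ch == "(") {
      depth <- depth + 1L
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else if (ch == ")") {
      if (depth == 0L) stop("malformed SMILES: unbalanced ')' at position ", i)
      depth <- depth - 1L
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .two_letter) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  if (depth > 0L) stop("malformed SMILES: unbalanced '(' left open")
  tokens
}

# ---- canonical attribute codes -------------------------------------------

.pad_dots <- function(s, width) {
  ifelse(nchar(s) >= width, s,
         paste0(s, strrep(".", width - nchar(s))))
}

#' Canonical attribute codes
#'
#' Attributes are identified by fixed-width 12-character codes padded with
#' dots: an S_k code is the token text padded to 12 (`"C..........."` is the
#' SMILES-atom C), an SS_k code is the first token padded to 4 followed by
#' the second token, padded to 12 (`"N...(......."` is the pair N-open
#' parenthesis), and an NNC code is `"NNC-<element>...<3 digits>."`
#' (`"NNC-C...321."`).
#'
#' @param token,token1,token2 Token text(s).
#' @param element Element symbol of the vertex.
#' @param code Integer nearest-neighbor code, 0-999.
#' @return A canonical code string.
#' @export
sk_code <- function(token) .pad_dots(token, 12L)

#' @rdname sk_code
#' @export
ssk_code <- function(token1, token2) {
  .pad_dots(paste0(.pad_dots(token1, 4L), token2), 12L)
}

#' @rdname sk_code
#' @export
nnc_key <- function(element, code) {
  stopifnot(code >= 0L, code <= 999L)
  .pad_dots(paste0(.pad_dots(paste0("NNC-", element), 8L),
                   sprintf("%03d", as.integer(code))), 12L)
}

# ---- attribute multisets --------------------------------------------------

# A multiset is a named integer vector (code -> count), sorted by code.
.ms_from_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(structure(integer(0L), names = character(0L)))
  }
  tab <- table(keys)
  out <- structure(as.integer(tab), names = names(tab))
  out[order(names(out))]
}

.ms_sum <- function(...) {
  parts <- list(...)
  all_names <- sort(unique(unlist(lapply(parts, names))))
  out <- structure(integer(length(all_names)), names = all_names)
  for (p in parts) {
    if (length(p)) out[names(p)] <- out[names(p)] + p
  }
  out
}

#' Single SMILES-atom attributes
#'
#' One S_k attribute per token, with multiplicity.
#'
#' @param tokens Token vector from [tokenize()].
#' @return Named integer vector: canonical S_k code -> count.
#' @export
sk_attributes <- function(tokens) {
  .ms_from_keys(vapply(tokens, sk_code, character(1L), USE.NAMES = FALSE))
}

#' Connected SMILES-atom pair attributes
#'
#' One SS_k attribute per adjacent token pair (sliding window of two, in
#' SMILES order -- pairs are directional, `"N("` and `"(N"` are distinct).
#'
#' @param tokens Token vector from [tokenize()].
#' @return Named integer vector: canonical SS_k code -> count.
#' @export
ssk_attributes <- function(tokens) {
  n <- length(tokens)
  if (n < 2L) return(.ms_from_keys(character(0L)))
  keys <- vapply(seq_len(n - 1L), function(i) {
    ssk_code(tokens[i], tokens[i + 1L])
  }, character(1L))
  .ms_from_keys(keys)
}

# ---- molecular graph ------------------------------------------------------

.bracket_element <- function(token) {
  # "[C@@H]" -> "C", "[nH]" -> "N", "[13C]" -> "C"
  m <- regmatches(token, regexpr("^\\[[0-9]*([A-Za-z][a-z]?)",
                                 token, perl = TRUE))
  el <- sub("^\\[[0-9]*", "", m)
  # A trailing lowercase letter only belongs to the element if the pair is a
  # real two-character symbol in our palette (Cl, Br); "[C@@H]"-style tokens
  # match just the capital.
  if (nchar(el) == 2L && !(el %in% .two_letter)) el <- substr(el, 1L, 1L)
  if (length(el) == 0L || nchar(el) == 0L) {
    stop("malformed SMILES: cannot read element in bracket atom ", token)
  }
  el <- paste0(toupper(substr(el, 1L, 1L)), substring(el, 2L))
  if (el == "H") stop("malformed SMILES: explicit hydrogen atom ", token,
                      " in a hydrogen-suppressed graph")
  el
}

#' Build the hydrogen-suppressed molecular graph of a SMILES string
#'
#' Parses chain, branch (parentheses) and ring-closure (digit) semantics into
#' a vertex/edge list. Bond-order symbols only connect — single, double,
#' triple and aromatic bonds all yield one edge, since only adjacency enters
#' the nearest-neighbor codes. Aromatic lowercase atoms become vertices of the
#' corresponding element; bracket atoms contribute their bare element.
#'
#' @param smiles A valid SMILES string.
#' @return An object of class `molecular_graph`: list with `vertices`
#'   (data.frame: `index`, `element`) and `edges` (two-column integer matrix
#'   of unordered vertex index pairs).
#' @examples
#' g <- build_graph("C1CC1")  # cyclopropane: 3 vertices, 3 edges
#' @export
build_graph <- function(smiles) {
  tokens <- tokenize(trimws(smiles))
  elements <- character(0L)
  edges <- matrix(integer(0L), ncol = 2L)
  prev <- NA_integer_
  branch_stack <- integer(0L)
  ring_open <- list()      # digit -> vertex index
  pending_bond <- FALSE

  add_edge <- function(a, b) {
    if (a == b) stop("malformed SMILES: ring closure forms a self-loop")
    e <- sort(c(a, b))
    if (nrow(edges) > 0L &&
        any(edges[, 1L] == e[1L] & edges[, 2L] == e[2L])) {
      return(invisible(NULL))
    }
    edges <<- rbind(edges, e)
    invisible(NULL)
  }

  for (tok in tokens) {
    first <- substr(tok, 1L, 1L)
    if (first == "[" || tok %in% .atom_letters || tok %in% .two_letter) {
      el <- if (first == "[") .bracket_element(tok) else {
        paste0(toupper(substr(tok, 1L, 1L)), substring(tok, 2L))
      }
      elements <- c(elements, el)
      v <- length(elements)
      if (!is.na(prev)) add_edge(prev, v)
      prev <- v
      pending_bond <- FALSE
    } else if (tok == "(") {
      if (pending_bond) stop("malformed SMILES: dangling bond before '('")
      if (is.na(prev)) stop("malformed SMILES: branch before any atom")
      branch_stack <- c(branch_stack, prev)
    } else if (tok == ")") {
      if (pending_bond) stop("malformed SMILES: dangling bond before ')'")
      if (length(branch_stack) == 0L) {
        stop("malformed SMILES: unbalanced ')'")
      }
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
    } else if (grepl("^[0-9]$", tok)) {
      if (is.na(prev)) stop("malformed SMILES: ring digit before any atom")
      if (!is.null(ring_open[[tok]])) {
        add_edge(ring_open[[tok]], prev)
        ring_open[[tok]] <- NULL
      } else {
        ring_open[[tok]] <- prev
      }
      pending_bond <- FALSE
    } else if (tok %in% .bond_chars) {
      pending_bond <- TRUE
    } else if (tok %in% c("@", "+")) {
      # stereo / charge marks outside brackets carry no adjacency
    } else {
      stop("malformed SMILES: unsupported token '", tok, "'")
    }
  }
  if (pending_bond) stop("malformed SMILES: dangling bond symbol at end")
  if (length(ring_open) > 0L) {
    stop("malformed SMILES: unmatched ring-closure digit ",
         paste(names(ring_open), collapse = ", "))
  }
  structure(
    list(vertices = data.frame(index = seq_along(elements),
                               element = elements,
                               stringsAsFactors = FALSE),
         edges = unname(edges)),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("Hydrogen-suppressed molecular graph:",
      nrow(x$vertices), "vertices,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Nearest Neighbor Code of a vertex
#'
#' `100 * N_T + 10 * N_C + N_X`, where `N_T` is the total number of
#' neighbors, `N_C` the number of carbon neighbors and `N_X` the number of
#' non-carbon neighbors (hydrogens never appear: the graph is
#' hydrogen-suppressed).
#'
#' @param n_total,n_carbon,n_noncarbon Non-negative neighbor counts with
#'   `n_total == n_carbon + n_noncarbon`.
#' @return Integer code.
#' @examples
#' nnc_code(3, 2, 1) # 321
#' @export
nnc_code <- function(n_total, n_carbon, n_noncarbon) {
  if (any(c(n_total, n_carbon, n_noncarbon) < 0L)) {
    stop("invariant violated: neighbor counts must be non-negative")
  }
  if (n_total != n_carbon + n_noncarbon) {
    stop("invariant violated: n_total must equal n_carbon + n_noncarbon")
  }
  as.integer(100L * n_total + 10L * n_carbon + n_noncarbon)
}

#' Nearest Neighbor Code attributes of a graph
#'
#' One NNC attribute per vertex, coded `"NNC-<element>...<code>."`.
#'
#' @param graph A [build_graph()] result.
#' @return Named integer vector: canonical NNC code -> count.
#' @export
nnc_attributes <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  nv <- nrow(graph$vertices)
  if (nv == 0L) return(.ms_from_keys(character(0L)))
  el <- graph$vertices$element
  keys <- vapply(seq_len(nv), function(v) {
    nb <- c(graph$edges[graph$edges[, 1L] == v, 2L],
            graph$edges[graph$edges[, 2L] == v, 1L])
    nt <- length(nb)
    nc <- sum(el[nb] == "C")
    nnc_key(el[v], nnc_code(nt, nc, nt - nc))
  }, character(1L))
  .ms_from_keys(keys)
}

#' Featurize a SMILES string
#'
#' The full attribute multiset of a compound: the multiset union of its S_k,
#' SS_k and NNC attributes. This is the set over which correlation weights
#' are summed in the optimal descriptor.
#'
#' @param smiles A valid SMILES string (leading/trailing whitespace ignored).
#' @return Named integer vector: canonical attribute code -> count, sorted by
#'   code.
#' @examples
#' featurize("C=O") # 3 S_k + 2 SS_k + 2 NNC instances
#' @export
featurize <- function(smiles) {
  s <- trimws(smiles)
  tokens <- tokenize(s)
  .ms_sum(sk_attributes(tokens),
          ssk_attributes(tokens),
          nnc_attributes(build_graph(s)))
}

#' Attribute count matrix of a dataset
#'
#' Featurizes every compound and assembles the compounds-by-attributes count
#' matrix used by the optimizer and the applicability-domain statistics.
#'
#' @param ds A dataset data.frame (see [read_dataset()]).
#' @return Integer matrix, rownames = compound ids, colnames = canonical
#'   attribute codes (sorted).
#' @export
attribute_matrix <- function(ds) {
  ms_list <- lapply(ds$smiles, featurize)
  codes <- sort(unique(unlist(lapply(ms_list, names))))
  m <- matrix(0L, nrow = nrow(ds), ncol = length(codes),
              dimnames = list(ds$id, codes))
  for (i in seq_along(ms_list)) {
    if (length(ms_list[[i]])) m[i, names(ms_list[[i]])] <- ms_list[[i]]
  }
  m
}
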