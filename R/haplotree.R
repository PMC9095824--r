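# Length of the revised Cambridge Reference Sequence (rCRS), the standard
# 1-based coordinate system for human mtDNA.
RCRS_LENGTH <- 16569L

BASES <- c("A", "C", "G", "T")

#' Parse a variant token
#'
#' Variant tokens follow PhyloTree-style notation:
#' `[ancestral]<position><derived>[!]`, e.g. `"C16223T"`, `"G11719A!"`,
#' `"16311C"`. The ancestral allele may be omitted when an rCRS reference
#' sequence is supplied; a trailing `"!"` marks a back-mutation (reversion
#' towards the ancestral state).
#'
#' @param token Character scalar, one variant token.
#' @param rcrs Optional character vector of length [RCRS_LENGTH] (one base
#'   per position) used to resolve an omitted ancestral allele.
#' @return A one-row data frame with columns `position` (integer),
#'   `ancestral`, `derived` (single bases) and `back_mutation` (logical).
#' @examples
#' parse_variant_token("C16223T!")
#' @export
parse_variant_token <- function(token, rcrs = NULL) {
  m <- regmatches(token, regexec("^([ACGT]?)([0-9]+)([ACGT])(!?)$", token))[[1]]
  if (length(m) == 0) {
    stop("malformed variant token: '", token, "'", call. = FALSE)
  }
  anc <- m[2]
  pos <- as.integer(m[3])
  der <- m[4]
  back <- m[5] == "!"
  if (pos < 1L || pos > RCRS_LENGTH) {
    stop("variant position out of rCRS range [1, ", RCRS_LENGTH, "]: ", pos,
         call. = FALSE)
  }
  if (anc == "") {
    if (is.null(rcrs)) {
      stop("token '", token, "' omits the ancestral allele and no rCRS ",
           "reference was supplied", call. = FALSE)
    }
    anc <- toupper(rcrs[pos])
  }
  if (anc == der) {
    stop("ancestral and derived alleles are identical in token '", token, "'",
         call. = FALSE)
  }
  data.frame(position = pos, ancestral = anc, derived = der,
             back_mutation = back, stringsAsFactors = FALSE)
}

format_variant <- function(v) {
  paste0(v$ancestral, v$position, v$derived, ifelse(v$back_mutation, "!", ""))
}

empty_variants <- function() {
  data.frame(position = integer(0), ancestral = character(0),
             derived = character(0), back_mutation = logical(0),
             stringsAsFactors = FALSE)
}

#' Parse a haplogroup tree file
#'
#' Reads a tab-indented haplogroup tree (PhyloTree export style). Each line
#' is `label <TAB> variant tokens`, with one extra leading tab per nesting
#' level; the first line is the root (conventionally `"rCRS"`) and carries
#' no defining variants. Variant tokens are space-separated and parsed by
#' [parse_variant_token()].
#'
#' @param text Character scalar (entire file content) or character vector of
#'   lines.
#' @param rcrs Optional rCRS base vector for tokens with omitted ancestral
#'   alleles (see [read_rcrs_fasta()]).
#' @return An object of class `haplo_tree`: a list with elements `root`
#'   (root label) and `nodes`, a named list of nodes, each holding `label`,
#'   `parent` (`NA` for the root), `children` (character vector, file
#'   order), `variants` (data frame as in [parse_variant_token()]) and
#'   `depth` (root = 0).
#' @export
parse_haplotree <- function(text, rcrs = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^#", lines)]
  if (length(lines) == 0) stop("empty tree file", call. = FALSE)

  nodes <- list()
  root <- NULL
  stack <- character(0) # labels by depth, stack[d + 1] = current node at depth d

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    depth <- 0L
    while (depth + 1L <= length(fields) && fields[depth + 1L] == "") {
      depth <- depth + 1L
    }
    label <- fields[depth + 1L]
    if (is.na(label) || label == "") {
      stop("line ", i, ": missing haplogroup label", call. = FALSE)
    }
    if (!is.null(nodes[[label]])) {
      stop("duplicate haplogroup label '", label, "' (line ", i, ")",
           call. = FALSE)
    }
    tokens <- character(0)
    if (length(fields) > depth + 1L) {
      rest <- paste(fields[(depth + 2L):length(fields)], collapse = " ")
      tokens <- strsplit(trimws(rest), "\\s+")[[1]]
      tokens <- tokens[tokens != ""]
    }
    variants <- if (length(tokens) == 0) {
      empty_variants()
    } else {
      do.call(rbind, lapply(tokens, function(tk) {
        tryCatch(parse_variant_token(tk, rcrs),
                 error = function(e) stop("line ", i, ": ",
                                          conditionMessage(e), call. = FALSE))
      }))
    }
    if (depth == 0L) {
      if (!is.null(root)) {
        stop("multiple roots: '", root, "' and '", label, "' (line ", i, ")",
             call. = FALSE)
      }
      if (nrow(variants) > 0) {
        stop("root node '", label, "' must not carry defining variants",
             call. = FALSE)
      }
      root <- label
      parent <- NA_character_
    } else {
      if (depth > length(stack)) {
        stop("line ", i, ": indentation skips a level", call. = FALSE)
      }
      parent <- stack[depth]
      nodes[[parent]]$children <- c(nodes[[parent]]$children, label)
    }
    nodes[[label]] <- list(label = label, parent = parent,
                           children = character(0), variants = variants,
                           depth = depth)
    stack <- c(stack[seq_len(depth)], label)
  }
  structure(list(root = root, nodes = nodes), class = "haplo_tree")
}

#' @describeIn parse_haplotree Read a tree from a file path.
#' @param path File path of the tree file.
#' @export
read_haplotree <- function(path, rcrs = NULL) {
  parse_haplotree(readLines(path, warn = FALSE), rcrs = rcrs)
}

#' Serialize a haplogroup tree
#'
#' Writes the canonical tab-indented form: depth-first traversal preserving
#' child order, each variant as `ancestral|position|derived` with a `!`
#' suffix for back-mutations. `parse_haplotree(serialize_haplotree(tree))`
#' reproduces `tree`; on files already in canonical form the round trip is
#' byte-identical.
#'
#' @param tree A `haplo_tree`.
#' @return Character vector of lines.
#' @export
serialize_haplotree <- function(tree) {
  out <- character(0)
  emit <- function(label) {
    node <- tree$nodes[[label]]
    toks <- if (nrow(node$variants)) {
      paste(format_variant(node$variants), collapse = " ")
    } else {
      NULL
    }
    line <- paste0(strrep("\t", node$depth), label,
                   if (!is.null(toks)) paste0("\t", toks) else "")
    out[[length(out) + 1L]] <<- line
    for (ch in node$children) emit(ch)
  }
  emit(tree$root)
  unlist(out)
}

#' @export
print.haplo_tree <- function(x, ...) {
  nvar <- sum(vapply(x$nodes, function(n) nrow(n$variants), integer(1)))
  cat("<haplo_tree> ", length(x$nodes), " haplogroups, ", nvar,
      " defining variants, root '", x$root, "'\n", sep = "")
  invisible(x)
}

tree_node <- function(tree, label) {
  node <- tree$nodes[[label]]
  if (is.null(node)) {
    stop("unknown haplogroup label '", label, "'", call. = FALSE)
  }
  node
}

#' Ancestor path of a haplogroup
#'
#' @param tree A `haplo_tree`.
#' @param label Haplogroup label in the tree.
#' @return Character vector of labels from the root down to `label`.
#' @export
ancestor_path <- function(tree, label) {
  node <- tree_node(tree, label)
  path <- character(0)
  while (!is.na(node$label)) {
    path <- c(node$label, path)
    if (is.na(node$parent)) break
    node <- tree$nodes[[node$parent]]
  }
  path
}

#' Expected variant profile of a haplogroup
#'
#' Applies all defining variants on the root-to-haplogroup path in order.
#' A later back-mutation at an already-mutated position restores the
#' original state, so only the final state per position is kept.
#'
#' @param tree A `haplo_tree`.
#' @param label Haplogroup label.
#' @return An object of class `expected_profile`: list with `haplogroup`,
#'   `states` (named character vector, names = positions, values = expected
#'   base) and `ref` (named character vector of the pre-path, i.e. rCRS,
#'   base at each touched position).
#' @export
expected_profile <- function(tree, label) {
  path <- ancestor_path(tree, label)
  states <- character(0)
  ref <- character(0)
  for (lab in path) {
    v <- tree$nodes[[lab]]$variants
    if (nrow(v) == 0) next
    for (k in seq_len(nrow(v))) {
      p <- as.character(v$position[k])
      if (is.na(ref[p])) ref[p] <- v$ancestral[k]
      states[p] <- v$derived[k]
    }
  }
  # positions whose final state equals the original reference base are not
  # derived states: a reversion cancels the earlier mutation
  structure(list(haplogroup = label, states = states, ref = ref),
            class = "expected_profile")
}

#' Macrohaplogroup of a haplogroup
#'
#' Walks up the ancestor path and returns the nearest label (self included)
#' belonging to the macrohaplogroup set; the root label if none is found.
#'
#' @param tree A `haplo_tree`.
#' @param label Haplogroup label.
#' @param macros Character vector of macrohaplogroup labels. Default: the
#'   deep mtDNA clades L0--L6, M, N and R.
#' @return A macrohaplogroup label (or the root label).
#' @export
macro_of <- function(tree, label,
                     macros = c(paste0("L", 0:6), "M", "N", "R")) {
  path <- rev(ancestor_path(tree, label)) # self first
  for (lab in path) {
    if (lab %in% macros) return(lab)
  }
  tree$root
}

#' Reference (rCRS) alleles implied by a tree
#'
#' For every position named by any defining variant, the rCRS base is the
#' ancestral allele of the variant closest to the root at that position.
#' Conflicting ancestral alleles at equal depth raise an error.
#'
#' @param tree A `haplo_tree`.
#' @return Named character vector, names = positions, values = bases.
#' @export
reference_alleles <- function(tree) {
  ref <- character(0)
  refdepth <- integer(0)
  for (node in tree$nodes) {
    v <- node$variants
    if (nrow(v) == 0) next
    for (k in seq_len(nrow(v))) {
      p <- as.character(v$position[k])
      if (is.na(ref[p]) || node$depth < refdepth[p]) {
        ref[p] <- v$ancestral[k]
        refdepth[p] <- node$depth
      } else if (node$depth == refdepth[p] && ref[p] != v$ancestral[k]) {
        stop("inconsistent ancestral alleles at position ", p, call. = FALSE)
      }
    }
  }
  ref
}

#' Read an rCRS FASTA file
#'
#' @param path Path to a single-sequence FASTA file of length 16569.
#' @return Character vector of single bases, indexable by 1-based position.
#' @export
read_rcrs_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seq <- toupper(paste(lines[!startsWith(lines, ">")], collapse = ""))
  strsplit(seq, "")[[1]]
}

#' Panel definition
#'
#' A diagnostic-site panel: the mtDNA positions assayed and the multiplex
#' pool each belongs to (MassARRAY-style assays amplify sites in pools).
#'
#' @param sites Data frame with integer columns `position` and `pool`.
#' @return The validated data frame with class `panel_definition`.
#' @export
panel_definition <- function(sites) {
  stopifnot(is.data.frame(sites), all(c("position", "pool") %in% names(sites)))
  sites$position <- as.integer(sites$position)
  sites$pool <- as.integer(sites$pool)
  if (anyDuplicated(sites$position)) {
    stop("panel positions must be unique", call. = FALSE)
  }
  if (any(sites$position < 1L | sites$position > RCRS_LENGTH)) {
    stop("panel positions must lie in [1, ", RCRS_LENGTH, "]", call. = FALSE)
  }
  class(sites) <- c("panel_definition", "data.frame")
  sites
}

#' @describeIn panel_definition Read a panel from a `position,pool` CSV.
#' @param path CSV file path.
#' @export
read_panel <- function(path) {
  panel_definition(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Packaged default haplogroup tree
#'
#' A curated synthetic stand-in subtree of the human mtDNA haplogroup tree
#' (~70 nodes) covering the haplogroups relevant to South Asian / West
#' Eurasian / East Eurasian ancestry assignment. Defining variants are
#' plausible rCRS-coordinate substitutions, not the published tree; supply
#' your own tree file via [read_haplotree()] for real analyses.
#'
#' @return A `haplo_tree`.
#' @export
default_haplotree <- function() {
  read_haplotree(system.file("extdata", "synthetic_haplotree.txt",
                             package = "paleoprov", mustWork = TRUE))
}

#' Packaged default diagnostic panel
#'
#' The 115-site panel matching the packaged synthetic tree, partitioned
#' into four multiplex pools of 23, 36, 31 and 25 sites.
#'
#' @return A `panel_definition`.
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "default_panel.csv",
                         package = "paleoprov", mustWork = TRUE))
}
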