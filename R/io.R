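#' Read a taxa table
#'
#' The taxa table is the taxonomic frame for the whole pipeline: one row
#' per species, mapping an opaque `species_id` to a species name and a
#' genus (plus any higher ranks in extra columns).
#'
#' @param path TSV file with header columns `species_id`, `species_name`,
#'   `genus`, and optionally further rank columns (e.g. `family`).
#' @return data frame with the same columns; `species_id` unique, every
#'   genus non-empty.
#' @export
read_taxa_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_taxa_table(tab)
}

validate_taxa_table <- function(tab) {
  need <- c("species_id", "species_name", "genus")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("taxa table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$species_id))
    stop("duplicated species_id in taxa table")
  if (any(is.na(tab$genus) | !nzchar(tab$genus)))
    stop("every species must have a non-empty genus")
  tab
}

#' @rdname read_taxa_table
#' @param tab taxa table data frame.
#' @export
write_taxa_table <- function(tab, path) {
  validate_taxa_table(tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fossil calibration table
#'
#' @param path TSV with header columns `calib_id`, `taxa` (comma-separated
#'   list of two or more species ids whose MRCA the fossil calibrates),
#'   `min_age` (Ma, required) and `max_age` (Ma, may be empty/NA).
#' @return data frame with columns `calib_id`, `taxa` (list column of
#'   character vectors), `min_age`, `max_age`.
#' @export
read_fossil_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("calib_id", "taxa", "min_age")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("fossil table missing column(s): ", paste(miss, collapse = ", "))
  if (!"max_age" %in% names(tab)) tab$max_age <- NA_real_
  tab$taxa <- lapply(strsplit(as.character(tab$taxa), ","), trimws)
  validate_fossil_table(tab)
}

validate_fossil_table <- function(tab) {
  if (any(lengths(tab$taxa) < 2)) stop("each calibration needs >= 2 taxa")
  if (any(!is.finite(tab$min_age) | tab$min_age <= 0)) stop("min_age must be > 0")
  bad <- !is.na(tab$max_age) & tab$max_age < tab$min_age
  if (any(bad)) stop("max_age < min_age for: ", paste(tab$calib_id[bad], collapse = ", "))
  tab
}

#' @rdname read_fossil_table
#' @param tab fossil calibration data frame (list-column `taxa`).
#' @export
write_fossil_table <- function(tab, path) {
  out <- data.frame(calib_id = tab$calib_id,
                    taxa = vapply(tab$taxa, paste, "", collapse = ","),
                    min_age = tab$min_age, max_age = tab$max_age)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sequence clusters ------------------------------------------------------

#' Construct a sequence cluster
#'
#' A cluster is a set of putatively homologous DNA sequences grouped
#' around a seed sequence (the single-linkage representative around which
#' the cluster was built).
#'
#' @param cluster_id cluster identifier.
#' @param seq_id,species_id parallel character vectors.
#' @param seqs character vector of residue strings, parallel to `seq_id`.
#' @param seed_id seq_id of the seed member (default: first).
#' @param aligned logical; all sequences must then be equal length.
#' @param seed_seq residues of the seed; required only when the seed
#'   record itself is no longer among the members (e.g. dropped during
#'   per-species reduction), so that seed-based cluster merging still
#'   has a sequence to compare.
#' @return object of class `seq_cluster`.
#' @export
seq_cluster <- function(cluster_id, seq_id, species_id, seqs,
                        seed_id = seq_id[1], aligned = FALSE,
                        seed_seq = NULL) {
  if (!length(seq_id)) stop("empty cluster")
  if (anyDuplicated(seq_id)) stop("duplicate seq_id in cluster ", cluster_id)
  if (length(species_id) != length(seq_id) || length(seqs) != length(seq_id))
    stop("seq_id, species_id and seqs must be parallel")
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in cluster ", cluster_id)
  for (i in seq_along(seqs)) check_iupac(seq_chars(seqs[i]), paste0("sequence ", seq_id[i]))
  if (aligned && length(unique(nchar(seqs))) != 1L)
    stop("aligned cluster must have equal-length sequences")
  if (seed_id %in% seq_id) seed_seq <- unname(seqs[match(seed_id, seq_id)])
  else if (is.null(seed_seq))
    stop("seed_id ", seed_id, " not among members of cluster ", cluster_id,
         " and no seed_seq given")
  structure(list(cluster_id = cluster_id, seed_id = seed_id,
                 seq_id = seq_id, species_id = species_id,
                 seqs = stats::setNames(seqs, seq_id), aligned = aligned,
                 seed_seq = toupper(seed_seq)),
            class = "seq_cluster")
}

#' @export
print.seq_cluster <- function(x, ...) {
  cat(sprintf("seq_cluster '%s': %d sequence(s), %d species, %s (seed %s)\n",
              x$cluster_id, length(x$seq_id), length(unique(x$species_id)),
              if (x$aligned) paste0("aligned (", nchar(x$seqs[1]), " cols)")
              else "unaligned", x$seed_id))
  invisible(x)
}

#' Read a FASTA file as a sequence cluster
#'
#' Headers must encode the sequence id and the species id; by default they
#' are `seqid|speciesid`.  The aligned flag is set when all sequences have
#' equal length and at least one contains a gap character.
#'
#' @param path FASTA file.
#' @param cluster_id id for the cluster (default: file name sans extension).
#' @param seed_id seed sequence id (default: first record).
#' @param header_sep separator between seq id and species id in headers.
#' @return a [seq_cluster()].
#' @export
read_fasta_cluster <- function(path, cluster_id = NULL, seed_id = NULL,
                               header_sep = "|") {
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       whole.header = TRUE),
    error = function(e) stop("empty or malformed FASTA file: ", path,
                             call. = FALSE))
  if (!length(recs)) stop("empty FASTA file: ", path)
  headers <- unname(vapply(recs, function(r) attr(r, "name") %||% "", ""))
  parts <- strsplit(headers, header_sep, fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("FASTA header(s) lack the '", header_sep, "' seq/species separator")
  seq_id <- unname(vapply(parts, `[`, "", 1L))
  species_id <- unname(vapply(parts, `[`, "", 2L))
  seqs <- toupper(unname(vapply(recs, function(r) as.character(r)[1], "")))
  lens <- nchar(seqs)
  aligned <- length(unique(lens)) == 1L && any(grepl("-", seqs, fixed = TRUE))
  seq_cluster(cluster_id %||% sub("\\.[^.]*$", "", basename(path)),
              seq_id, species_id, seqs,
              seed_id = seed_id %||% seq_id[1], aligned = aligned)
}

#' @rdname read_fasta_cluster
#' @param cluster a `seq_cluster`.
#' @export
write_fasta_cluster <- function(cluster, path, header_sep = "|") {
  lines <- character(2L * length(cluster$seq_id))
  lines[c(TRUE, FALSE)] <- paste0(">", cluster$seq_id, header_sep, cluster$species_id)
  lines[c(FALSE, TRUE)] <- unname(cluster$seqs)
  writeLines(lines, path)
  invisible(path)
}

# An "alignment" downstream of species reduction is a character matrix,
# one row per species (rownames = species_id), one column per site.
cluster_to_alignment <- function(cluster) {
  if (!cluster$aligned) stop("cluster ", cluster$cluster_id, " is not aligned")
  if (anyDuplicated(cluster$species_id))
    stop("cluster ", cluster$cluster_id,
         " has several sequences per species; reduce it first")
  m <- do.call(rbind, lapply(unname(cluster$seqs), seq_chars))
  rownames(m) <- cluster$species_id
  m
}

alignment_to_cluster <- function(mat, cluster_id, seed_id = rownames(mat)[1]) {
  seq_cluster(cluster_id, rownames(mat), rownames(mat),
              apply(mat, 1, paste, collapse = ""),
              seed_id = seed_id, aligned = TRUE)
}

read_alignment <- function(path) {
  cl <- read_fasta_cluster(path)
  if (!cl$aligned) {
    if (length(unique(nchar(cl$seqs))) != 1L)
      stop("sequences in ", path, " differ in length: not an alignment")
    cl$aligned <- TRUE
  }
  cluster_to_alignment(cl)
}

write_alignment <- function(mat, path) {
  cl <- alignment_to_cluster(mat, "aln")
  write_fasta_cluster(cl, path)
}

# ---- Newick with bracket annotations ---------------------------------------

parse_comment <- function(txt) {
  # txt: inside of "[&...]"; returns list(support, hpd, areas, extra)
  out <- list(support = NA_real_, hpd = NULL, areas = NULL, extra = NA_character_)
  # split on commas at brace depth 0 only, so {a,b} survives intact
  fields <- character()
  depth <- 0L; buf <- ""
  for (ch in strsplit(txt, "")[[1]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "," && depth == 0L) { fields <- c(fields, buf); buf <- "" }
    else buf <- paste0(buf, ch)
  }
  if (nzchar(buf)) fields <- c(fields, buf)
  extras <- character()
  for (f in fields) {
    kv <- strsplit(f, "=", fixed = TRUE)[[1]]
    key <- kv[1]; val <- if (length(kv) > 1) paste(kv[-1], collapse = "=") else ""
    if (key == "support") out$support <- as.numeric(val)
    else if (key == "hpd_min") { out$hpd <- c(as.numeric(val), out$hpd[2] %||% NA_real_) }
    else if (key == "hpd_max") { out$hpd <- c(out$hpd[1] %||% NA_real_, as.numeric(val)) }
    else if (key == "areas") {
      out$areas <- strsplit(gsub("[{}]", "", val), ",")[[1]]
    } else if (grepl("^\\{[^}]*,[^}]*\\}$", val)) {
      # a generic two-number interval is read as an HPD
      nums <- as.numeric(strsplit(gsub("[{}]", "", val), ",")[[1]])
      if (length(nums) == 2 && !anyNA(nums) && is.null(out$hpd)) out$hpd <- nums
      else extras <- c(extras, f)
    } else extras <- c(extras, f)
  }
  if (!is.null(out$hpd) && anyNA(out$hpd))
    stop("incomplete HPD annotation: ", txt)
  if (length(extras)) out$extra <- paste(extras, collapse = ",")
  out
}

#' Read a tree from a Newick file
#'
#' Three dialects are understood: plain Newick; Newick with numeric
#' internal-node labels interpreted as support values; and Newick with
#' figtree-style bracket comments (`[&support=0.9,hpd_min=1.5,
#' hpd_max=2.5,areas={a,b}]`) on nodes.  A bare two-number interval such
#' as `[&age={1.5,2.5}]` is read as an HPD; unrecognized annotations are
#' kept verbatim and written back on round-trip.
#'
#' @param path file, or a literal Newick string via `text`.
#' @param text Newick string (overrides `path`).
#' @param dialect one of `"auto"`, `"plain"`, `"support"`, `"annotated"`.
#' @param ultrametric if `"required"`, error unless all tips are at equal
#'   depth from the root.
#' @param allow_negative keep negative branch lengths instead of erroring.
#' @return a [chronogram()].
#' @export
read_tree <- function(path = NULL, text = NULL,
                      dialect = c("auto", "plain", "support", "annotated"),
                      ultrametric = c("no", "required"),
                      allow_negative = FALSE) {
  dialect <- match.arg(dialect)
  ultrametric <- match.arg(ultrametric)
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (dialect == "auto")
    dialect <- if (grepl("[&", text, fixed = TRUE)) "annotated" else "plain"
  comments <- list()
  if (dialect == "annotated") {
    m <- gregexpr("\\[&[^]]*\\]", text)[[1]]
    if (m[1] != -1) {
      frags <- regmatches(text, gregexpr("\\[&[^]]*\\]", text))[[1]]
      for (k in seq_along(frags))
        comments[[k]] <- parse_comment(substr(frags[k], 3, nchar(frags[k]) - 1L))
      for (k in seq_along(frags))
        text <- sub(frags[k], sprintf("@@%d@@", k), text, fixed = TRUE)
    }
  }
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy)) stop("could not parse Newick (unbalanced parentheses?)")
  if (!allow_negative && !is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch length in input tree")
  ntip <- ape::Ntip(phy)
  data <- NULL
  strip <- function(lab) sub("@@[0-9]+@@", "", lab)
  marker <- function(lab) {
    m <- regmatches(lab, regexpr("@@([0-9]+)@@", lab))
    if (length(m)) as.integer(gsub("@", "", m)) else NA_integer_
  }
  if (length(comments)) {
    rows <- list()
    labs <- c(phy$tip.label, phy$node.label %||% rep("", phy$Nnode))
    for (i in seq_along(labs)) {
      k <- marker(labs[i])
      if (!is.na(k)) {
        cm <- comments[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          node = i, support = cm$support,
          hpd_min = if (!is.null(cm$hpd)) cm$hpd[1] else NA_real_,
          hpd_max = if (!is.null(cm$hpd)) cm$hpd[2] else NA_real_,
          areas = if (length(cm$areas)) paste(cm$areas, collapse = ",") else NA_character_,
          extra = cm$extra, stringsAsFactors = FALSE)
      }
    }
    phy$tip.label <- strip(phy$tip.label)
    if (!is.null(phy$node.label)) phy$node.label <- strip(phy$node.label)
    if (length(rows)) data <- do.call(rbind, rows)
  }
  if (dialect == "support" && !is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    if (any(!is.na(sup))) {
      if (max(sup, na.rm = TRUE) > 1) sup <- sup / 100
      idx <- which(!is.na(sup))
      data <- data.frame(node = ntip + idx, support = sup[idx],
                         stringsAsFactors = FALSE)
    }
    phy$node.label <- NULL
  }
  if (!is.null(phy$node.label) && all(!nzchar(phy$node.label))) phy$node.label <- NULL
  if (ultrametric == "required") {
    depth <- ape::node.depth.edgelength(phy)[seq_len(ntip)]
    if (diff(range(depth)) > 1e-6 * max(depth, 1))
      stop("tree is not ultrametric but ultrametric interpretation was required")
  }
  chronogram(phy, data)
}

format_num <- function(x, digits = 10) {
  out <- formatC(x, digits = digits, format = "g")
  gsub(" ", "", out)
}

node_comment <- function(row) {
  parts <- character()
  if (!is.na(row$support)) parts <- c(parts, paste0("support=", format_num(row$support)))
  if (!is.na(row$hpd_min)) parts <- c(parts, paste0("hpd_min=", format_num(row$hpd_min)),
                                      paste0("hpd_max=", format_num(row$hpd_max)))
  if (!is.na(row$areas)) parts <- c(parts, paste0("areas={", row$areas, "}"))
  if (!is.na(row$extra)) parts <- c(parts, row$extra)
  if (!length(parts)) "" else paste0("[&", paste(parts, collapse = ","), "]")
}

#' Write a tree to Newick
#'
#' Annotations (support, HPD intervals, area sets and any preserved
#' unknown fields) are emitted as bracket comments after the node label.
#'
#' @param x a `chronogram` or `phylo`.
#' @param path output file; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the path (or the Newick string when `path` is `NULL`).
#' @export
write_tree <- function(x, path = NULL, digits = 10) {
  chron <- as_chronogram(x)
  phy <- ape::reorder.phylo(chron$phy, "cladewise")
  ntip <- ape::Ntip(phy)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  elen <- phy$edge.length
  cmt <- function(node) {
    a <- anno_lookup(chron, node)
    if (is.null(a)) "" else node_comment(a)
  }
  rec <- function(node, edge_idx) {
    blen <- if (is.null(edge_idx)) "" else paste0(":", format_num(elen[edge_idx], digits))
    if (node <= ntip) return(paste0(phy$tip.label[node], cmt(node), blen))
    inner <- vapply(kids[[as.character(node)]],
                    function(e) rec(phy$edge[e, 2], e), "")
    lab <- if (!is.null(phy$node.label)) phy$node.label[node - ntip] else ""
    paste0("(", paste(inner, collapse = ","), ")", lab, cmt(node), blen)
  }
  nwk <- paste0(rec(ntip + 1L, NULL), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

# ---- supermatrix writers ----------------------------------------------------

sanitize_label <- function(x) gsub("[^A-Za-z0-9_.]", "_", x)

check_partitions <- function(partitions, ncols) {
  p <- as.data.frame(partitions)
  need <- c("name", "start", "end")
  if (!all(need %in% names(p))) stop("partitions need columns name, start, end")
  p <- p[order(p$start), ]
  if (any(p$start > p$end)) stop("partition start > end")
  covered <- integer()
  for (i in seq_len(nrow(p))) {
    cols <- p$start[i]:p$end[i]
    if (length(intersect(covered, cols))) stop("overlapping partitions")
    covered <- c(covered, cols)
  }
  if (!setequal(covered, seq_len(ncols)))
    stop("partitions must tile columns 1..", ncols)
  p
}

#' Write a supermatrix with its partition table
#'
#' @param mat character matrix, rows = taxa (rownames), columns = sites;
#'   missing data already coded `?`.
#' @param partitions data frame `name`, `start`, `end`; 1-based inclusive
#'   column ranges that tile the matrix.
#' @param path output file.  For `format = "phylip"` a sidecar
#'   `<path>.partitions` is written with lines `name = start-end`.
#' @param format `"phylip"` (relaxed) or `"nexus"` (data + sets blocks).
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(mat, partitions, path,
                              format = c("phylip", "nexus")) {
  format <- match.arg(format)
  p <- check_partitions(partitions, ncol(mat))
  labels <- sanitize_label(rownames(mat))
  if (anyDuplicated(labels))
    stop("taxon label collision after sanitization: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rows <- apply(mat, 1, paste, collapse = "")
  if (format == "phylip") {
    pad <- max(nchar(labels)) + 2L
    lines <- c(paste(nrow(mat), ncol(mat)),
               paste0(formatC(labels, width = -pad), rows))
    writeLines(lines, path)
    writeLines(sprintf("%s = %d-%d", p$name, p$start, p$end),
               paste0(path, ".partitions"))
  } else {
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mat), ncol(mat)),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX",
               paste0("    ", formatC(labels, width = -(max(nchar(labels)) + 2L)), rows),
               "  ;", "END;", "BEGIN SETS;",
               sprintf("  CHARSET %s = %d-%d;", p$name, p$start, p$end),
               "END;")
    writeLines(lines, path)
  }
  invisible(path)
}
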