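# Toy fixture suite: a set of small shell-seeded components plus seedable
# data generators, standing in for real sequence-analysis pipelines so that
# every engine feature — sweeps, breakpoints, forced dependencies,
# scatter/gather over BED intervals with merge, boilerplates, keywords,
# custom output directories — is exercisable with no external tools or
# downloads.

# shared POSIX argument parser for seed scripts: turns `--key v1 [v2 ...]`
# into shell variables, bare `--key` into key=1
BASH_ARGPARSE <- c(
  'while [ $# -gt 0 ]; do',
  '  k=${1#--}; shift',
  '  v=""',
  '  while [ $# -gt 0 ] && [ "${1#--}" = "$1" ]; do v="$v $1"; shift; done',
  '  v=${v# }',
  '  if [ -z "$v" ]; then v=1; fi',
  '  eval "$k=\\$v"',
  'done')

fixture_component_specs <- function() {
  list(
    comp_textgen = list(
      doc = "generate n lines of deterministic text",
      params = list(
        param_spec("n", "argument", default = 20L),
        param_spec("tag", "argument", default = "fixture"),
        param_spec("delay", "argument"),
        param_spec("upper", "flag"),
        param_spec("out_file", "output_file", required = TRUE)),
      seed = c(
        'if [ -n "${delay:-}" ]; then sleep "$delay"; fi',
        'awk -v n="$n" -v t="$tag" \'BEGIN{for(i=1;i<=n;i++) printf "line %d tag %s\\n", i, t}\' > "$out_file"',
        'if [ "${upper:-0}" = 1 ]; then tr "a-z" "A-Z" < "$out_file" > "$out_file.u" && mv "$out_file.u" "$out_file"; fi')),
    comp_copy = list(
      doc = "copy a file",
      params = list(
        param_spec("in_file", "input_file", required = TRUE),
        param_spec("out_file", "output_file", required = TRUE)),
      seed = 'cp "$in_file" "$out_file"'),
    comp_linecount = list(
      doc = "count lines of a file",
      params = list(
        param_spec("in_file", "input_file", required = TRUE),
        param_spec("out_file", "output_file", required = TRUE)),
      seed = 'wc -l < "$in_file" | tr -d " " > "$out_file"'),
    comp_interval_count = list(
      doc = "count variants per genomic interval (0-based half-open BED); parallelizable",
      params = list(
        param_spec("variants", "input_file", required = TRUE),
        param_spec("intervals", "input_file", required = TRUE),
        param_spec("out_file", "output_file", required = TRUE)),
      parallelization = list(split_param = "intervals", merge_strategy = "concat"),
      seed = paste0(
        "awk 'NR==FNR {c[NR]=$1; s[NR]=$2; e[NR]=$3; n=NR; next}\n",
        "     {for (i=1;i<=n;i++) if ($1==c[i] && $2>=s[i] && $2<e[i]) cnt[i]++}\n",
        "     END {for (i=1;i<=n;i++) printf \"%s\\t%d\\t%d\\t%d\\n\", c[i], s[i], e[i], cnt[i]+0}' ",
        '"$intervals" "$variants" > "$out_file"')),
    comp_region_table = list(
      doc = "headered per-interval variant table; parallelizable with header-aware merge",
      params = list(
        param_spec("variants", "input_file", required = TRUE),
        param_spec("intervals", "input_file", required = TRUE),
        param_spec("out_file", "output_file", required = TRUE)),
      parallelization = list(split_param = "intervals",
                             merge_strategy = "concat_skip_header"),
      seed = paste0(
        'printf "chrom\\tstart\\tend\\tcount\\n" > "$out_file"\n',
        "awk 'NR==FNR {c[NR]=$1; s[NR]=$2; e[NR]=$3; n=NR; next}\n",
        "     {for (i=1;i<=n;i++) if ($1==c[i] && $2>=s[i] && $2<e[i]) cnt[i]++}\n",
        "     END {for (i=1;i<=n;i++) printf \"%s\\t%d\\t%d\\t%d\\n\", c[i], s[i], e[i], cnt[i]+0}' ",
        '"$intervals" "$variants" >> "$out_file"')),
    comp_table_merge = list(
      doc = "concatenate delimited tables keeping a single header (fan-in input)",
      params = list(
        param_spec("in_files", "input_file", required = TRUE),
        param_spec("out_file", "output_file", required = TRUE)),
      seed = "awk 'FNR==1 && NR!=1 {next} {print}' $in_files > \"$out_file\""),
    comp_fail_on_demand = list(
      doc = "fail iff a trigger file exists; otherwise write a marker output",
      params = list(
        param_spec("trigger", "argument", required = TRUE),
        param_spec("out_file", "output_file", required = TRUE)),
      seed = c(
        'if [ -e "$trigger" ]; then echo "failure trigger present: $trigger" >&2; exit 3; fi',
        'echo "ok" > "$out_file"'))
  )
}

write_fixture_component <- function(name, spec, dest) {
  sc <- make_component_template(name, dest)
  comp <- component_definition(
    name = name,
    seed_command = "bash {COMPONENT_DIR}/seed/run.sh",
    params = spec$params,
    parallelization = spec$parallelization,
    version = "1.0.0")
  write_component_definition(comp, sc$definition_file)
  seed_file <- file.path(sc$seed_dir, "run.sh")
  writeLines(c("#!/usr/bin/env bash", "set -eu", BASH_ARGPARSE, spec$seed), seed_file)
  Sys.chmod(seed_file, "0755")
  writeLines(c(sprintf("# %s", name), "", spec$doc), sc$docs)
  sc$root_dir
}

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Write a toy BED file of sorted, non-overlapping intervals
#'
#' Intervals follow the BED convention: 0-based, half-open, tab-separated
#' `chrom start end`, sorted by chromosome then start, pairwise
#' non-overlapping. Draws from the current RNG state.
#'
#' @param path output path.
#' @param n number of intervals.
#' @param chroms chromosome names to distribute intervals over.
#' @param chrom_len coordinate upper bound per chromosome.
#' @return invisibly, the interval data frame.
#' @export
write_toy_bed <- function(path, n = 10L, chroms = c("chr1", "chr2"),
                          chrom_len = 10000L) {
  per <- table(factor(sort(sample(chroms, n, replace = TRUE)), levels = sort(chroms)))
  rows <- lapply(names(per), function(ch) {
    k <- per[[ch]]
    if (!k) return(NULL)
    # 2k distinct sorted coordinates give k strictly increasing intervals
    b <- sort(sample.int(chrom_len, 2L * k))
    data.frame(chrom = ch, start = b[seq(1, 2 * k, 2)] - 1L,
               end = b[seq(2, 2 * k, 2)], stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}

#' Write a toy variant position table
#'
#' Two tab-separated columns, `chrom` and 0-based `pos`, the shape a toy
#' per-interval counter consumes. Draws from the current RNG state.
#'
#' @param path output path.
#' @param n number of variant rows.
#' @param chroms chromosome names.
#' @param chrom_len coordinate upper bound.
#' @return invisibly, the variant data frame.
#' @export
write_toy_variants <- function(path, n = 200L, chroms = c("chr1", "chr2"),
                               chrom_len = 10000L) {
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   pos = sample.int(chrom_len, n, replace = TRUE) - 1L,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(df)
}

#' Write toy FASTA-like sequence text
#'
#' Random A/C/G/T records with `>seq_i` headers. Plain-text stand-in for
#' real sequence inputs; draws from the current RNG state.
#'
#' @param path output path.
#' @param n_seq number of records.
#' @param len sequence length per record.
#' @export
write_toy_fasta <- function(path, n_seq = 5L, len = 80L) {
  lines <- unlist(lapply(seq_len(n_seq), function(i) {
    c(sprintf(">seq_%d", i),
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a toy headered table
#'
#' @param path output path.
#' @param n number of data rows.
#' @param label value written in the `label` column.
#' @export
write_toy_table <- function(path, n = 10L, label = "a") {
  df <- data.frame(id = seq_len(n), label = label,
                   value = round(stats::runif(n), 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate the complete toy fixture suite
#'
#' Writes the toy components (`comp_textgen`, `comp_copy`,
#' `comp_linecount`, `comp_interval_count`, `comp_region_table`,
#' `comp_table_merge`, `comp_fail_on_demand`) under `<dest>/components/`
#' and seeded toy data — FASTA-like text, a sorted non-overlapping BED, a
#' variant position table, two headered tables — under `<dest>/data/`.
#' Deterministic: the same seed reproduces a byte-identical tree; the
#' caller's RNG state is left untouched.
#'
#' @param dest writable destination directory.
#' @param seed integer seed for the data generators.
#' @param n_intervals intervals in the generated BED.
#' @param n_variants rows in the generated variant table.
#' @return a `fixture_suite`: list with `components_dir`, `data_dir`,
#'   named `data` paths, and the loaded component `registry`.
#' @export
generate_fixture_suite <- function(dest, seed = 1L, n_intervals = 10L,
                                   n_variants = 200L) {
  comp_dir <- file.path(dest, "components")
  data_dir <- file.path(dest, "data")
  dir.create(comp_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- fixture_component_specs()
  for (name in names(specs)) {
    if (!dir.exists(file.path(comp_dir, name))) {
      write_fixture_component(name, specs[[name]], comp_dir)
    }
  }
  data <- with_local_seed(seed, {
    paths <- list(
      fasta = file.path(data_dir, "reads.fasta"),
      bed = file.path(data_dir, "targets.bed"),
      variants = file.path(data_dir, "variants.tsv"),
      table_a = file.path(data_dir, "table_a.tsv"),
      table_b = file.path(data_dir, "table_b.tsv"))
    write_toy_fasta(paths$fasta)
    write_toy_bed(paths$bed, n = n_intervals)
    write_toy_variants(paths$variants, n = n_variants)
    write_toy_table(paths$table_a, label = "a")
    write_toy_table(paths$table_b, label = "b")
    paths
  })
  structure(list(components_dir = comp_dir, data_dir = data_dir, data = data,
                 registry = load_components(comp_dir)),
            class = "fixture_suite")
}
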