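# shared fixtures: tiny count tables and geometries built in code

unit_geometry <- function(...) {
  microscope_geometry(dilution_factor = 1, filtered_volume_ml = 1,
                      filter_effective_area_um2 = 1, field_area_um2 = 1, ...)
}

# long counts table from a per-replicate list of per-field counts;
# `classes` maps diameter class -> matrix-like of counts [replicate, field]
make_counts <- function(sample_id = "S", single = NULL, classes = list()) {
  rows <- list()
  add <- function(rep, field, type, cls, count) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, replicate_id = rep, field_id = field,
      object_type = type, diameter_class_um = cls, count = count)
  }
  if (!is.null(single)) {
    for (r in seq_len(nrow(single)))
      for (f in seq_len(ncol(single)))
        add(r, f, "single_cell", NA_real_, single[r, f])
  }
  for (cls in names(classes)) {
    m <- classes[[cls]]
    for (r in seq_len(nrow(m)))
      for (f in seq_len(ncol(m)))
        add(r, f, "aggregate", as.numeric(cls), m[r, f])
  }
  do.call(rbind, rows)
}

# probe table with constant dapi/probe counts over fields
make_probes <- function(sample_id = "S", probe_id = "EelMS932",
                        replicate_id, field_id, object_type,
                        diameter_class_um, probe_count, dapi_count) {
  data.frame(sample_id = sample_id, probe_id = probe_id,
             replicate_id = replicate_id, field_id = field_id,
             object_type = object_type,
             diameter_class_um = diameter_class_um,
             probe_count = probe_count, dapi_count = dapi_count)
}
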