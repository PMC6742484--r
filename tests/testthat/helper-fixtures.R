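# shared fixtures, built once per test run
fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, cache)) {
      assign(name, switch(name,
        tubulin = build_tubulin_shape(),
        binder_pocket = build_binder_shape("pocket"),
        binder_face = build_binder_shape("face"),
        mt_blunt = build_microtubule("blunt", 207),
        mt_tapered = build_microtubule("tapered", 207),
        mt_sheet = build_microtubule("sheet", 207),
        mt_single = build_microtubule("single_dimer"),
        mt_small = build_microtubule("blunt", 39),
        sites_blunt = enumerate_sites(fx("mt_blunt"), "pocket"),
        sites_single = enumerate_sites(fx("mt_single"), "pocket"),
        model_pocket = diffusion_model(fx("binder_pocket")),
        stop("unknown fixture ", name)), cache)
    }
    get(name, cache)
  }
})

unit_cube <- function() {
  v <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  convex_shape(v, list(c(1, 2, 4, 3), c(5, 6, 8, 7), c(1, 2, 6, 5),
                       c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 4, 8, 6)),
               name = "cube")
}

pocket_anchor_matrix <- function(binder, roles) {
  nm <- c(ll = "iface_ll", ul = "iface_ul", lr = "iface_lr",
          ur = "iface_ur", face = "iface")
  t(vapply(roles, function(r) binder$anchors[[nm[r]]], numeric(3)))
}
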