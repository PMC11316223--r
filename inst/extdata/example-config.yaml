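# Example pipeline configuration for `run_all()` / the run-all subcommand.
# Conditions are simulated; `scene` entries accept any scene_spec() argument.
seed: 1
anchors:
  control: control
  myo: TGFb
params:
  autocontrast_saturated: 0.0035
  tophat_radius: 5
  min_nucleus_area: 50
  max_nucleus_area: 500
  min_fa_area: 0.4
  exclude_border: true
conditions:
  - name: control
    n_images: 2
    scene:
      n_cells: 6
      cell_length: [55.0, 6.0]
      fa_radial_placement: 0.85
  - name: TGFb
    n_images: 2
    scene:
      n_cells: 6
      cell_length: [75.0, 6.0]
      cell_width: [24.0, 3.0]
      fa_per_cell: [12.0, 1.0]
      fa_radial_placement: 0.25
  - name: 20x20
    n_images: 2
    pattern: {width: 20.0, spacing: 20.0, angle: 30.0}
    scene:
      n_cells: 6
      cell_length: [80.0, 8.0]
      cell_width: [14.0, 2.0]
      cell_orientation_concentration: 4.0
      fa_radial_placement: 0.6
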