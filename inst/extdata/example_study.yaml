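# Example study configuration for `pamp run` / run_pipeline():
# one simulated control and two treated arms in the same batch.
seed: 7
acquisition:
  pixel_size_um: 0.65
  frame_interval_min: 5
  wavelength_um: 0.66
  alpha_um3_per_pg: 0.18
movies:
  - condition: CNT
    batch: 1
    is_control: true
    sim: {n_cells: 20, n_frames: 241}
  - condition: DRUG_A
    batch: 1
    sim: {n_cells: 20, n_frames: 241, drug_effect: 0.5}
  - condition: DRUG_B
    batch: 1
    sim: {n_cells: 20, n_frames: 241, drug_effect: 0.8, drug_circ_shift: 0.3}
analysis:
  periods: [[0, 10], [10, 20]]
  eval_times_h: [10, 20]
  min_area_um2: 50
  max_link_um: 15
  max_gap: 2
  min_steps: 12
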