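# Default session design: a free recording, one minute each of eyes-open
# and eyes-closed rest, then two oddball blocks separated by a recovery
# rest. Marker codes: standard = 1, oddball = 2 (0 = no event; task
# boundaries are coded 100 + task index at start, 200 + task index at end).
format_version: 1
device: virtual
seed: 1
marker_map:
  standard: 1
  oddball: 2
tasks:
- kind: free_recording
  duration_s: 30
- kind: rest_eyes_open
  duration_s: 60
- kind: rest_eyes_closed
  duration_s: 60
- kind: oddball
  n_trials: 200
  p_oddball: 0.1
  isi_s: 1.0
  stim_duration_s: 0.2
- kind: rest_eyes_open
  duration_s: 30
- kind: oddball
  n_trials: 200
  p_oddball: 0.1
  isi_s: 1.0
  stim_duration_s: 0.2
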