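# Packaged case systems

Two Brazilian SAMU (mobile emergency medical service) systems, `bauru/` and
`ribeirao_preto/`, transcribed from the published demand table (hourly call
rates per sub atom), the per-type average response times (minutes) and the
inter-atom mean journey-time matrices (minutes).

Schema (comma-separated, header row, atoms numbered from 1):

- `atoms.csv` — `atom_id,name`
- `arrival_rates.csv` — `atom_id,priority{serious|regular},rate_per_hour`
- `travel_times.csv` — `from_atom,to_atom,minutes` (row = server base,
  column = call location; not required symmetric; intra-atom entries on a
  par with inter-atom ones)
- `servers.csv` — `server_type{BSU|ASU},count,dedicated{0|1},base_atom,mean_service_time_min`

Notes:

- The source narrative calls Bauru atom A1 "Nações" while its demand table
  lists atom 1 as Geisel; the files follow the demand table's ordering.
- The source does not print which atoms host the dedicated advanced units
  (ASU); both Bauru ASUs and the single Ribeirão Preto ASU are pinned to
  atom 1 here. This `base_atom` value is a synthetic stand-in choice, not a
  published datum.
- Per-ambulance response times are published, but the aggregation model
  treats co-located same-type servers as homogeneous, so the files carry the
  published per-type averages.
- The Bauru intra-atom entry for atom 6 is printed with a decimal comma
  ("7,6") in the source and is transcribed as 7.6.
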