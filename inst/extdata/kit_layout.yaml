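# Golden Gate TALEN kit layout. Array module plasmids are named by RVD
# and slot (position within each 10-slot array); the final repeat of an
# arm comes from a last-half-repeat plasmid. Edit to match a kit
# revision; no code change is needed.
min_repeats: 12
max_repeats: 31
slots_per_array: 10
module_pattern: "p{rvd}{slot}"
last_repeat_pattern: "pLR_{rvd}"
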