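# Stratified sampling frame of the Swedish Skagerrak flat-oyster inventory:
# areal extent (km^2) of each area x depth-band cell and the survey that
# covers it. Shallow-band extents already carry the 0.5 m lower-bound
# correction (5/6 of the 0-3 m chart interval).
shallow_area_correction: false
strata:
  - {area_label: "Area 1", depth_label: "0.5-3", areal_extent_km2: 15.93, survey_id: coastal}
  - {area_label: "Area 1", depth_label: "3-6",   areal_extent_km2: 6.37,  survey_id: coastal}
  - {area_label: "Area 1", depth_label: "6-10",  areal_extent_km2: 8.68,  survey_id: coastal}
  - {area_label: "Area 2", depth_label: "0.5-3", areal_extent_km2: 13.35, survey_id: coastal}
  - {area_label: "Area 2", depth_label: "3-6",   areal_extent_km2: 6.42,  survey_id: coastal}
  - {area_label: "Area 2", depth_label: "6-10",  areal_extent_km2: 10.42, survey_id: coastal}
  - {area_label: "Area 3", depth_label: "0.5-3", areal_extent_km2: 12.35, survey_id: coastal}
  - {area_label: "Area 3", depth_label: "3-6",   areal_extent_km2: 6.78,  survey_id: coastal}
  - {area_label: "Area 3", depth_label: "6-10",  areal_extent_km2: 8.93,  survey_id: coastal}
  - {area_label: "Area 4", depth_label: "0.5-3", areal_extent_km2: 20.65, survey_id: coastal}
  - {area_label: "Area 4", depth_label: "3-6",   areal_extent_km2: 7.91,  survey_id: coastal}
  - {area_label: "Area 4", depth_label: "6-10",  areal_extent_km2: 12.91, survey_id: coastal}
  - {area_label: "Koster", depth_label: "0.5-3", areal_extent_km2: 7.47,  survey_id: koster}
  - {area_label: "Koster", depth_label: "3-6",   areal_extent_km2: 5.86,  survey_id: koster}
  - {area_label: "Koster", depth_label: "6-10",  areal_extent_km2: 7.93,  survey_id: koster}
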