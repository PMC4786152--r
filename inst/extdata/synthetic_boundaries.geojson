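{
  "type": "FeatureCollection",
  "note": "Synthetic, highly simplified stand-in boundaries for demos and tests. Shapes are crude convex sketches placed near the real countries; they are NOT real borders. Real use should point at an ISO-3-keyed boundary source such as CShapes or Natural Earth.",
  "features": [
    {"type": "Feature", "properties": {"iso_a3": "MEX", "name": "Mexico (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-117, 32], [-97, 29], [-87, 21], [-92, 15], [-105, 19], [-117, 32]]]}},
    {"type": "Feature", "properties": {"iso_a3": "HTI", "name": "Haiti (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-74.5, 20.1], [-71.7, 19.9], [-71.6, 18.0], [-74.4, 18.2], [-74.5, 20.1]]]}},
    {"type": "Feature", "properties": {"iso_a3": "PER", "name": "Peru (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-81.3, -4.2], [-75.0, -0.2], [-69.9, -4.0], [-69.0, -9.5], [-70.0, -17.3], [-75.8, -15.0], [-81.3, -4.2]]]}},
    {"type": "Feature", "properties": {"iso_a3": "BRA", "name": "Brazil (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-60.0, 4.5], [-51.0, 4.0], [-35.0, -7.0], [-39.0, -17.0], [-48.0, -25.5], [-53.5, -33.0], [-57.5, -30.0], [-58.0, -20.0], [-65.0, -10.0], [-69.5, -4.5], [-60.0, 4.5]]]}},
    {"type": "Feature", "properties": {"iso_a3": "ARG", "name": "Argentina (synthetic)"},
     "geometry": {"type": "Polygon", "coordinates": [[[-65.5, -22.0], [-58.0, -24.5], [-57.5, -34.0], [-62.0, -40.5], [-65.0, -54.5], [-68.5, -52.5], [-70.5, -40.0], [-68.5, -27.0], [-65.5, -22.0]]]}},
    {"type": "Feature", "properties": {"iso_a3": "CHL", "name": "Chile (synthetic)"},
     "geometry": {"type": "MultiPolygon", "coordinates": [
       [[[-70.5, -17.6], [-68.5, -27.0], [-70.5, -40.0], [-73.8, -43.0], [-71.5, -30.0], [-70.5, -17.6]]],
       [[[-73.8, -43.5], [-72.0, -52.0], [-69.0, -55.5], [-74.5, -53.0], [-75.5, -47.0], [-73.8, -43.5]]]
     ]}}
  ]
}
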