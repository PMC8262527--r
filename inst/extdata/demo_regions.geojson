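{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {
        "id": "plum-south",
        "fruit": "plum",
        "synthetic": true
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-8.2, 38],
            [-7.3, 38],
            [-7.3, 39.3],
            [-8.2, 39.3],
            [-8.2, 38]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "id": "apple-west",
        "fruit": "apple",
        "synthetic": true
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-9.2, 39.5],
            [-8.4, 39.5],
            [-8.4, 40.1],
            [-9.2, 40.1],
            [-9.2, 39.5]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "id": "apple-north",
        "fruit": "apple",
        "synthetic": true
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-7.8, 41.2],
            [-6.9, 41.2],
            [-6.9, 42],
            [-7.8, 42],
            [-7.8, 41.2]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "id": "apple-east",
        "fruit": "apple",
        "synthetic": true
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-7.2, 39.6],
            [-6.3, 39.6],
            [-6.3, 40.3],
            [-7.2, 40.3],
            [-7.2, 39.6]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "id": "apple-inland",
        "fruit": "apple",
        "synthetic": true
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-7.7, 38.9],
            [-6.8, 38.9],
            [-6.8, 39.3],
            [-7.7, 39.3],
            [-7.7, 38.9]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "id": "apple-estuary",
        "fruit": "apple",
        "synthetic": true
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-9.2, 38],
            [-8.4, 38],
            [-8.4, 38.5],
            [-9.2, 38.5],
            [-9.2, 38]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "id": "pear-west",
        "fruit": "pear",
        "synthetic": true
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-9.7, 38.9],
            [-9.3, 38.9],
            [-9.3, 40.1],
            [-9.7, 40.1],
            [-9.7, 38.9]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "id": "orange-south",
        "fruit": "orange",
        "synthetic": true
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-8.2, 36.2],
            [-6.8, 36.2],
            [-6.8, 37],
            [-8.2, 37],
            [-8.2, 36.2]
          ]
        ]
      }
    }
  ]
}
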