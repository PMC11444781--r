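{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"id":"1","population":11352.5534700602,"count":106},"geometry":{"type":"Polygon","coordinates":[[[0.646672789356671,0.746256053661798],[1,0.746256053661798],[1,1],[0.646672789356671,1],[0.646672789356671,0.746256053661798]]]}},{"type":"Feature","properties":{"id":"2","population":47049.940029392,"count":463},"geometry":{"type":"Polygon","coordinates":[[[0.273623305769702,0.301126844759679],[0.646672789356671,0.301126844759679],[0.646672789356671,0.469323635986075],[0.273623305769702,0.469323635986075],[0.273623305769702,0.301126844759679]]]}},{"type":"Feature","properties":{"id":"3","population":5652.84499432892,"count":62},"geometry":{"type":"Polygon","coordinates":[[[0.646672789356671,0],[1,0],[1,0.15379011265178],[0.646672789356671,0.15379011265178],[0.646672789356671,0]]]}},{"type":"Feature","properties":{"id":"4","population":78930.2818023134,"count":786},"geometry":{"type":"Polygon","coordinates":[[[0.646672789356671,0.15379011265178],[1,0.15379011265178],[1,0.384709333628416],[0.646672789356671,0.384709333628416],[0.646672789356671,0.15379011265178]]]}},{"type":"Feature","properties":{"id":"5","population":28743.8603071496,"count":1753},"geometry":{"type":"Polygon","coordinates":[[[0,0],[0.273623305769702,0],[0.273623305769702,0.228903733110687],[0,0.228903733110687],[0,0]]]}},{"type":"Feature","properties":{"id":"6","population":52958.6706438567,"count":3251},"geometry":{"type":"Polygon","coordinates":[[[0,0.228903733110687],[0.273623305769702,0.228903733110687],[0.273623305769702,0.469323635986075],[0,0.469323635986075],[0,0.228903733110687]]]}},{"type":"Feature","properties":{"id":"7","population":27141.7426539119,"count":248},"geometry":{"type":"Polygon","coordinates":[[[0.646672789356671,0.384709333628416],[1,0.384709333628416],[1,0.52987917179165],[0.646672789356671,0.52987917179165],[0.646672789356671,0.384709333628416]]]}},{"type":"Feature","properties":{"id":"8","population":79752.7770407032,"count":849},"geometry":{"type":"Polygon","coordinates":[[[0.646672789356671,0.52987917179165],[1,0.52987917179165],[1,0.746256053661798],[0.646672789356671,0.746256053661798],[0.646672789356671,0.52987917179165]]]}},{"type":"Feature","properties":{"id":"9","population":72951.5990195796,"count":745},"geometry":{"type":"Polygon","coordinates":[[[0,0.469323635986075],[0.239866848059497,0.469323635986075],[0.239866848059497,0.691912191411517],[0,0.691912191411517],[0,0.469323635986075]]]}},{"type":"Feature","properties":{"id":"10","population":79155.4358042777,"count":800},"geometry":{"type":"Polygon","coordinates":[[[0,0.691912191411517],[0.239866848059497,0.691912191411517],[0.239866848059497,1],[0,1],[0,0.691912191411517]]]}},{"type":"Feature","properties":{"id":"11","population":9923.43045771122,"count":96},"geometry":{"type":"Polygon","coordinates":[[[0.239866848059497,0.709199279272092],[0.476564274825763,0.709199279272092],[0.476564274825763,1],[0.239866848059497,1],[0.239866848059497,0.709199279272092]]]}},{"type":"Feature","properties":{"id":"12","population":52027.9068860691,"count":513},"geometry":{"type":"Polygon","coordinates":[[[0.476564274825763,0.709199279272092],[0.646672789356671,0.709199279272092],[0.646672789356671,1],[0.476564274825763,1],[0.476564274825763,0.709199279272092]]]}},{"type":"Feature","properties":{"id":"13","population":41785.6280645356,"count":2507},"geometry":{"type":"Polygon","coordinates":[[[0.273623305769702,0],[0.414968197141024,0],[0.414968197141024,0.301126844759679],[0.273623305769702,0.301126844759679],[0.273623305769702,0]]]}},{"type":"Feature","properties":{"id":"14","population":77826.8309670966,"count":792},"geometry":{"type":"Polygon","coordinates":[[[0.414968197141024,0],[0.646672789356671,0],[0.646672789356671,0.301126844759679],[0.414968197141024,0.301126844759679],[0.414968197141024,0]]]}},{"type":"Feature","properties":{"id":"15","population":32166.5635635145,"count":329},"geometry":{"type":"Polygon","coordinates":[[[0.239866848059497,0.469323635986075],[0.437588501596227,0.469323635986075],[0.437588501596227,0.709199279272092],[0.239866848059497,0.709199279272092],[0.239866848059497,0.469323635986075]]]}},{"type":"Feature","properties":{"id":"16","population":55999.5095839258,"count":558},"geometry":{"type":"Polygon","coordinates":[[[0.437588501596227,0.469323635986075],[0.646672789356671,0.469323635986075],[0.646672789356671,0.709199279272092],[0.437588501596227,0.709199279272092],[0.437588501596227,0.469323635986075]]]}}]}
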