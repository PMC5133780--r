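# Lebedev-Laikov angular quadrature point sets (unit sphere).
# Auto-generated tables; columns x, y, z, w with sum(w) = 4*pi.
.lebedev_orders <- c(6, 26, 50, 110, 194, 302, 434)
.lebedev_tables <- new.env(parent = emptyenv())
.lebedev_tables[["6"]] <- matrix(c(1, 0, 0, 2.0943951023932, -1, 0, 0, 2.0943951023932, 0, 1, 0, 2.0943951023932, 0, -1, 0, 2.0943951023932, 0, 0, 1, 2.0943951023932, 0, 0, -1, 2.0943951023932), ncol = 4L, byrow = TRUE)
.lebedev_tables[["26"]] <- matrix(c(1, 0, 0, 0.59839860068377, -1, 0, 0, 0.59839860068377, 0, 1, 0, 0.59839860068377, 0, -1, 0, 0.59839860068377, 0, 0, 1, 0.59839860068377, 0, 0, -1, 0.59839860068377, 0, 0.707106781186548, 0.707106781186548, 0.478718880547016, 0, -0.707106781186548, 0.707106781186548, 0.478718880547016, 0, 0.707106781186548, -0.707106781186548, 0.478718880547016, 0, -0.707106781186548, -0.707106781186548, 0.478718880547016, 0.707106781186548, 0, 0.707106781186548, 0.478718880547016, 0.707106781186548, 0, -0.707106781186548, 0.478718880547016, -0.707106781186548, 0, 0.707106781186548, 0.478718880547016, -0.707106781186548, 0, -0.707106781186548, 0.478718880547016, 0.707106781186548, 0.707106781186548, 0, 0.478718880547016, -0.707106781186548, 0.707106781186548, 0, 0.478718880547016, 0.707106781186548, -0.707106781186548, 0, 0.478718880547016, -0.707106781186548, -0.707106781186548, 0, 0.478718880547016, 0.577350269189626, 0.577350269189626, 0.577350269189626, 0.403919055461545, -0.577350269189626, 0.577350269189626, 0.577350269189626, 0.403919055461545, 0.577350269189626, -0.577350269189626, 0.577350269189626, 0.403919055461545, 0.577350269189626, 0.577350269189626, -0.577350269189626, 0.403919055461545, -0.577350269189626, -0.577350269189626, 0.577350269189626, 0.403919055461545, 0.577350269189626, -0.577350269189626, -0.577350269189626, 0.403919055461545, -0.577350269189626, 0.577350269189626, -0.577350269189626, 0.403919055461545, -0.577350269189626, -0.577350269189626, -0.577350269189626, 0.403919055461545), ncol = 4L, byrow = TRUE)
.lebedev_tables[["50"]] <- matrix(c(1, 0, 0, 0.159572960182339, -1, 0, 0, 0.159572960182339, 0, 1, 0, 0.159572960182339, 0, -1, 0, 0.159572960182339, 0, 0, 1, 0.159572960182339, 0, 0, -1, 0.159572960182339, 0, 0.707106781186548, 0.707106781186548, 0.28368526254638, 0, -0.707106781186548, 0.707106781186548, 0.28368526254638, 0, 0.707106781186548, -0.707106781186548, 0.28368526254638, 0, -0.707106781186548, -0.707106781186548, 0.28368526254638, 0.707106781186548, 0, 0.707106781186548, 0.28368526254638, 0.707106781186548, 0, -0.707106781186548, 0.28368526254638, -0.707106781186548, 0, 0.707106781186548, 0.28368526254638, -0.707106781186548, 0, -0.707106781186548, 0.28368526254638, 0.707106781186548, 0.707106781186548, 0, 0.28368526254638, -0.707106781186548, 0.707106781186548, 0, 0.28368526254638, 0.707106781186548, -0.707106781186548, 0, 0.28368526254638, -0.707106781186548, -0.707106781186548, 0, 0.28368526254638, 0.577350269189626, 0.577350269189626, 0.577350269189626, 0.265071880146639, -0.577350269189626, 0.577350269189626, 0.577350269189626, 0.265071880146639, 0.577350269189626, -0.577350269189626, 0.577350269189626, 0.265071880146639, 0.577350269189626, 0.577350269189626, -0.577350269189626, 0.265071880146639, -0.577350269189626, -0.577350269189626, 0.577350269189626, 0.265071880146639, 0.577350269189626, -0.577350269189626, -0.577350269189626, 0.265071880146639, -0.577350269189626, 0.577350269189626, -0.577350269189626, 0.265071880146639, -0.577350269189626, -0.577350269189626, -0.577350269189626, 0.265071880146639, 0.301511344577764, 0.301511344577764, 0.904534033733291, 0.253505610897311, -0.301511344577764, 0.301511344577764, 0.904534033733291, 0.253505610897311, 0.301511344577764, -0.301511344577764, 0.904534033733291, 0.253505610897311, 0.301511344577764, 0.301511344577764, -0.904534033733291, 0.253505610897311, -0.301511344577764, -0.301511344577764, 0.904534033733291, 0.253505610897311, -0.301511344577764, 0.301511344577764, -0.904534033733291, 0.253505610897311, 0.301511344577764, -0.301511344577764, -0.904534033733291, 0.253505610897311, -0.301511344577764, -0.301511344577764, -0.904534033733291, 0.253505610897311, -0.301511344577764, 0.904534033733291, 0.301511344577764, 0.253505610897311, 0.301511344577764, -0.904534033733291, 0.301511344577764, 0.253505610897311, 0.301511344577764, 0.904534033733291, -0.301511344577764, 0.253505610897311, -0.301511344577764, -0.904534033733291, 0.301511344577764, 0.253505610897311, -0.301511344577764, 0.904534033733291, -0.301511344577764, 0.253505610897311, 0.301511344577764, -0.904534033733291, -0.301511344577764, 0.253505610897311, -0.301511344577764, -0.904534033733291, -0.301511344577764, 0.253505610897311, 0.301511344577764, 0.904534033733291, 0.301511344577764, 0.253505610897311, 0.904534033733291, 0.301511344577764, 0.301511344577764, 0.253505610897311, -0.904534033733291, 0.301511344577764, 0.301511344577764, 0.253505610897311, 0.904534033733291, -0.301511344577764, 0.301511344577764, 0.253505610897311, 0.904534033733291, 0.301511344577764, -0.301511344577764, 0.253505610897311, -0.904534033733291, -0.301511344577764, 0.301511344577764, 0.253505610897311, -0.904534033733291, 0.301511344577764, -0.301511344577764, 0.253505610897311, 0.904534033733291, -0.301511344577764, -0.301511344577764, 0.253505610897311, -0.904534033733291, -0.301511344577764, -0.301511344577764, 0.253505610897311), ncol = 4L, byrow = TRUE)
.lebedev_tables[["110"]] <- matrix(c(1, 0, 0, 0.0481074658513966, -1, 0, 0, 0.0481074658513966, 0, 1, 0, 0.0481074658513966, 0, -1, 0, 0.0481074658513966, 0, 0, 1, 0.0481074658513966, 0, 0, -1, 0.0481074658513966, 0.577350269189626, 0.577350269189626, 0.577350269189626, 0.12307173528167, -0.577350269189626, 0.577350269189626, 0.577350269189626, 0.12307173528167, 0.577350269189626, -0.577350269189626, 0.577350269189626, 0.12307173528167, 0.577350269189626, 0.577350269189626, -0.577350269189626, 0.12307173528167, -0.577350269189626, -0.577350269189626, 0.577350269189626, 0.12307173528167, 0.577350269189626, -0.577350269189626, -0.577350269189626, 0.12307173528167, -0.577350269189626, 0.577350269189626, -0.577350269189626, 0.12307173528167, -0.577350269189626, -0.577350269189626, -0.577350269189626, 0.12307173528167, 0.185115635344736, 0.185115635344736, 0.965124035086594, 0.10319173408833, -0.185115635344736, 0.185115635344736, 0.965124035086594, 0.10319173408833, 0.185115635344736, -0.185115635344736, 0.965124035086594, 0.10319173408833, 0.185115635344736, 0.185115635344736, -0.965124035086594, 0.10319173408833, -0.185115635344736, -0.185115635344736, 0.965124035086594, 0.10319173408833, -0.185115635344736, 0.185115635344736, -0.965124035086594, 0.10319173408833, 0.185115635344736, -0.185115635344736, -0.965124035086594, 0.10319173408833, -0.185115635344736, -0.185115635344736, -0.965124035086594, 0.10319173408833, -0.185115635344736, 0.965124035086594, 0.185115635344736, 0.10319173408833, 0.185115635344736, -0.965124035086594, 0.185115635344736, 0.10319173408833, 0.185115635344736, 0.965124035086594, -0.185115635344736, 0.10319173408833, -0.185115635344736, -0.965124035086594, 0.185115635344736, 0.10319173408833, -0.185115635344736, 0.965124035086594, -0.185115635344736, 0.10319173408833, 0.185115635344736, -0.965124035086594, -0.185115635344736, 0.10319173408833, -0.185115635344736, -0.965124035086594, -0.185115635344736, 0.10319173408833, 0.185115635344736, 0.965124035086594, 0.185115635344736, 0.10319173408833, 0.965124035086594, 0.185115635344736, 0.185115635344736, 0.10319173408833, -0.965124035086594, 0.185115635344736, 0.185115635344736, 0.10319173408833, 0.965124035086594, -0.185115635344736, 0.185115635344736, 0.10319173408833, 0.965124035086594, 0.185115635344736, -0.185115635344736, 0.10319173408833, -0.965124035086594, -0.185115635344736, 0.185115635344736, 0.10319173408833, -0.965124035086594, 0.185115635344736, -0.185115635344736, 0.10319173408833, 0.965124035086594, -0.185115635344736, -0.185115635344736, 0.10319173408833, -0.965124035086594, -0.185115635344736, -0.185115635344736, 0.10319173408833, 0.690421048382292, 0.690421048382292, 0.215957291845848, 0.124945096872513, -0.690421048382292, 0.690421048382292, 0.215957291845848, 0.124945096872513, 0.690421048382292, -0.690421048382292, 0.215957291845848, 0.124945096872513, 0.690421048382292, 0.690421048382292, -0.215957291845848, 0.124945096872513, -0.690421048382292, -0.690421048382292, 0.215957291845848, 0.124945096872513, -0.690421048382292, 0.690421048382292, -0.215957291845848, 0.124945096872513, 0.690421048382292, -0.690421048382292, -0.215957291845848, 0.124945096872513, -0.690421048382292, -0.690421048382292, -0.215957291845848, 0.124945096872513, -0.690421048382292, 0.215957291845848, 0.690421048382292, 0.124945096872513, 0.690421048382292, -0.215957291845848, 0.690421048382292, 0.124945096872513, 0.690421048382292, 0.215957291845848, -0.690421048382292, 0.124945096872513, -0.690421048382292, -0.215957291845848, 0.690421048382292, 0.124945096872513, -0.690421048382292, 0.215957291845848, -0.690421048382292, 0.124945096872513, 0.690421048382292, -0.215957291845848, -0.690421048382292, 0.124945096872513, -0.690421048382292, -0.215957291845848, -0.690421048382292, 0.124945096872513, 0.690421048382292, 0.215957291845848, 0.690421048382292, 0.124945096872513, 0.215957291845848, 0.690421048382292, 0.690421048382292, 0.124945096872513, -0.215957291845848, 0.690421048382292, 0.690421048382292, 0.124945096872513, 0.215957291845848, -0.690421048382292, 0.690421048382292, 0.124945096872513, 0.215957291845848, 0.690421048382292, -0.690421048382292, 0.124945096872513, -0.215957291845848, -0.690421048382292, 0.690421048382292, 0.124945096872513, -0.215957291845848, 0.690421048382292, -0.690421048382292, 0.124945096872513, 0.215957291845848, -0.690421048382292, -0.690421048382292, 0.124945096872513, -0.215957291845848, -0.690421048382292, -0.690421048382292, 0.124945096872513, 0.395689473055942, 0.395689473055942, 0.828769981252592, 0.120580249028528, -0.395689473055942, 0.395689473055942, 0.828769981252592, 0.120580249028528, 0.395689473055942, -0.395689473055942, 0.828769981252592, 0.120580249028528, 0.395689473055942, 0.395689473055942, -0.828769981252592, 0.120580249028528, -0.395689473055942, -0.395689473055942, 0.828769981252592, 0.120580249028528, -0.395689473055942, 0.395689473055942, -0.828769981252592, 0.120580249028528, 0.395689473055942, -0.395689473055942, -0.828769981252592, 0.120580249028528, -0.395689473055942, -0.395689473055942, -0.828769981252592, 0.120580249028528, -0.395689473055942, 0.828769981252592, 0.395689473055942, 0.120580249028528, 0.395689473055942, -0.828769981252592, 0.395689473055942, 0.120580249028528, 0.395689473055942, 0.828769981252592, -0.395689473055942, 0.120580249028528, -0.395689473055942, -0.828769981252592, 0.395689473055942, 0.120580249028528, -0.395689473055942, 0.828769981252592, -0.395689473055942, 0.120580249028528, 0.395689473055942, -0.828769981252592, -0.395689473055942, 0.120580249028528, -0.395689473055942, -0.828769981252592, -0.395689473055942, 0.120580249028528, 0.395689473055942, 0.828769981252592, 0.395689473055942, 0.120580249028528, 0.828769981252592, 0.395689473055942, 0.395689473055942, 0.120580249028528, -0.828769981252592, 0.395689473055942, 0.395689473055942, 0.120580249028528, 0.828769981252592, -0.395689473055942, 0.395689473055942, 0.120580249028528, 0.828769981252592, 0.395689473055942, -0.395689473055942, 0.120580249028528, -0.828769981252592, -0.395689473055942, 0.395689473055942, 0.120580249028528, -0.828769981252592, 0.395689473055942, -0.395689473055942, 0.120580249028528, 0.828769981252592, -0.395689473055942, -0.395689473055942, 0.120580249028528, -0.828769981252592, -0.395689473055942, -0.395689473055942, 0.120580249028528, 0.47836902881215, 0.878158910604066, 0, 0.121830917385521, -0.47836902881215, 0.878158910604066, 0, 0.121830917385521, 0.47836902881215, -0.878158910604066, 0, 0.121830917385521, -0.47836902881215, -0.878158910604066, 0, 0.121830917385521, 0.878158910604066, 0.47836902881215, 0, 0.121830917385521, -0.878158910604066, 0.47836902881215, 0, 0.121830917385521, 0.878158910604066, -0.47836902881215, 0, 0.121830917385521, -0.878158910604066, -0.47836902881215, 0, 0.121830917385521, 0.47836902881215, 0, 0.878158910604066, 0.121830917385521, -0.47836902881215, 0, 0.878158910604066, 0.121830917385521, 0.47836902881215, 0, -0.878158910604066, 0.121830917385521, -0.47836902881215, 0, -0.878158910604066, 0.121830917385521, 0.878158910604066, 0, 0.47836902881215, 0.121830917385521, -0.878158910604066, 0, 0.47836902881215, 0.121830917385521, 0.878158910604066, 0, -0.47836902881215, 0.121830917385521, -0.878158910604066, 0, -0.47836902881215, 0.121830917385521, 0, 0.47836902881215, 0.878158910604066, 0.121830917385521, 0, -0.47836902881215, 0.878158910604066, 0.121830917385521, 0, 0.47836902881215, -0.878158910604066, 0.121830917385521, 0, -0.47836902881215, -0.878158910604066, 0.121830917385521, 0, 0.878158910604066, 0.47836902881215, 0.121830917385521, 0, -0.878158910604066, 0.47836902881215, 0.121830917385521, 0, 0.878158910604066, -0.47836902881215, 0.121830917385521, 0, -0.878158910604066, -0.47836902881215, 0.121830917385521), ncol = 4L, byrow = TRUE)
.lebedev_tables[["194"]] <- matrix(c(1, 0, 0, 0.0223975506210385, -1, 0, 0, 0.0223975506210385, 0, 1, 0, 0.0223975506210385, 0, -1, 0, 0.0223975506210385, 0, 0, 1, 0.0223975506210385, 0, 0, -1, 0.0223975506210385, 0, 0.707106781186548, 0.707106781186548, 0.0718407589348474, 0, -0.707106781186548, 0.707106781186548, 0.0718407589348474, 0, 0.707106781186548, -0.707106781186548, 0.0718407589348474, 0, -0.707106781186548, -0.707106781186548, 0.0718407589348474, 0.707106781186548, 0, 0.707106781186548, 0.0718407589348474, 0.707106781186548, 0, -0.707106781186548, 0.0718407589348474, -0.707106781186548, 0, 0.707106781186548, 0.0718407589348474, -0.707106781186548, 0, -0.707106781186548, 0.0718407589348474, 0.707106781186548, 0.707106781186548, 0, 0.0718407589348474, -0.707106781186548, 0.707106781186548, 0, 0.0718407589348474, 0.707106781186548, -0.707106781186548, 0, 0.0718407589348474, -0.707106781186548, -0.707106781186548, 0, 0.0718407589348474, 0.577350269189626, 0.577350269189626, 0.577350269189626, 0.0700371986012485, -0.577350269189626, 0.577350269189626, 0.577350269189626, 0.0700371986012485, 0.577350269189626, -0.577350269189626, 0.577350269189626, 0.0700371986012485, 0.577350269189626, 0.577350269189626, -0.577350269189626, 0.0700371986012485, -0.577350269189626, -0.577350269189626, 0.577350269189626, 0.0700371986012485, 0.577350269189626, -0.577350269189626, -0.577350269189626, 0.0700371986012485, -0.577350269189626, 0.577350269189626, -0.577350269189626, 0.0700371986012485, -0.577350269189626, -0.577350269189626, -0.577350269189626, 0.0700371986012485, 0.671297344269523, 0.671297344269523, 0.314196994182586, 0.0704810541680701, -0.671297344269523, 0.671297344269523, 0.314196994182586, 0.0704810541680701, 0.671297344269523, -0.671297344269523, 0.314196994182586, 0.0704810541680701, 0.671297344269523, 0.671297344269523, -0.314196994182586, 0.0704810541680701, -0.671297344269523, -0.671297344269523, 0.314196994182586, 0.0704810541680701, -0.671297344269523, 0.671297344269523, -0.314196994182586, 0.0704810541680701, 0.671297344269523, -0.671297344269523, -0.314196994182586, 0.0704810541680701, -0.671297344269523, -0.671297344269523, -0.314196994182586, 0.0704810541680701, -0.671297344269523, 0.314196994182586, 0.671297344269523, 0.0704810541680701, 0.671297344269523, -0.314196994182586, 0.671297344269523, 0.0704810541680701, 0.671297344269523, 0.314196994182586, -0.671297344269523, 0.0704810541680701, -0.671297344269523, -0.314196994182586, 0.671297344269523, 0.0704810541680701, -0.671297344269523, 0.314196994182586, -0.671297344269523, 0.0704810541680701, 0.671297344269523, -0.314196994182586, -0.671297344269523, 0.0704810541680701, -0.671297344269523, -0.314196994182586, -0.671297344269523, 0.0704810541680701, 0.671297344269523, 0.314196994182586, 0.671297344269523, 0.0704810541680701, 0.314196994182586, 0.671297344269523, 0.671297344269523, 0.0704810541680701, -0.314196994182586, 0.671297344269523, 0.671297344269523, 0.0704810541680701, 0.314196994182586, -0.671297344269523, 0.671297344269523, 0.0704810541680701, 0.314196994182586, 0.671297344269523, -0.671297344269523, 0.0704810541680701, -0.314196994182586, -0.671297344269523, 0.671297344269523, 0.0704810541680701, -0.314196994182586, 0.671297344269523, -0.671297344269523, 0.0704810541680701, 0.314196994182586, -0.671297344269523, -0.671297344269523, 0.0704810541680701, -0.314196994182586, -0.671297344269523, -0.671297344269523, 0.0704810541680701, 0.289246562757544, 0.289246562757544, 0.912509096867474, 0.0648203268035105, -0.289246562757544, 0.289246562757544, 0.912509096867474, 0.0648203268035105, 0.289246562757544, -0.289246562757544, 0.912509096867474, 0.0648203268035105, 0.289246562757544, 0.289246562757544, -0.912509096867474, 0.0648203268035105, -0.289246562757544, -0.289246562757544, 0.912509096867474, 0.0648203268035105, -0.289246562757544, 0.289246562757544, -0.912509096867474, 0.0648203268035105, 0.289246562757544, -0.289246562757544, -0.912509096867474, 0.0648203268035105, -0.289246562757544, -0.289246562757544, -0.912509096867474, 0.0648203268035105, -0.289246562757544, 0.912509096867474, 0.289246562757544, 0.0648203268035105, 0.289246562757544, -0.912509096867474, 0.289246562757544, 0.0648203268035105, 0.289246562757544, 0.912509096867474, -0.289246562757544, 0.0648203268035105, -0.289246562757544, -0.912509096867474, 0.289246562757544, 0.0648203268035105, -0.289246562757544, 0.912509096867474, -0.289246562757544, 0.0648203268035105, 0.289246562757544, -0.912509096867474, -0.289246562757544, 0.0648203268035105, -0.289246562757544, -0.912509096867474, -0.289246562757544, 0.0648203268035105, 0.289246562757544, 0.912509096867474, 0.289246562757544, 0.0648203268035105, 0.912509096867474, 0.289246562757544, 0.289246562757544, 0.0648203268035105, -0.912509096867474, 0.289246562757544, 0.289246562757544, 0.0648203268035105, 0.912509096867474, -0.289246562757544, 0.289246562757544, 0.0648203268035105, 0.912509096867474, 0.289246562757544, -0.289246562757544, 0.0648203268035105, -0.912509096867474, -0.289246562757544, 0.289246562757544, 0.0648203268035105, -0.912509096867474, 0.289246562757544, -0.289246562757544, 0.0648203268035105, 0.912509096867474, -0.289246562757544, -0.289246562757544, 0.0648203268035105, -0.912509096867474, -0.289246562757544, -0.289246562757544, 0.0648203268035105, 0.444693317871744, 0.444693317871744, 0.777493219314767, 0.069350927593711, -0.444693317871744, 0.444693317871744, 0.777493219314767, 0.069350927593711, 0.444693317871744, -0.444693317871744, 0.777493219314767, 0.069350927593711, 0.444693317871744, 0.444693317871744, -0.777493219314767, 0.069350927593711, -0.444693317871744, -0.444693317871744, 0.777493219314767, 0.069350927593711, -0.444693317871744, 0.444693317871744, -0.777493219314767, 0.069350927593711, 0.444693317871744, -0.444693317871744, -0.777493219314767, 0.069350927593711, -0.444693317871744, -0.444693317871744, -0.777493219314767, 0.069350927593711, -0.444693317871744, 0.777493219314767, 0.444693317871744, 0.069350927593711, 0.444693317871744, -0.777493219314767, 0.444693317871744, 0.069350927593711, 0.444693317871744, 0.777493219314767, -0.444693317871744, 0.069350927593711, -0.444693317871744, -0.777493219314767, 0.444693317871744, 0.069350927593711, -0.444693317871744, 0.777493219314767, -0.444693317871744, 0.069350927593711, 0.444693317871744, -0.777493219314767, -0.444693317871744, 0.069350927593711, -0.444693317871744, -0.777493219314767, -0.444693317871744, 0.069350927593711, 0.444693317871744, 0.777493219314767, 0.444693317871744, 0.069350927593711, 0.777493219314767, 0.444693317871744, 0.444693317871744, 0.069350927593711, -0.777493219314767, 0.444693317871744, 0.444693317871744, 0.069350927593711, 0.777493219314767, -0.444693317871744, 0.444693317871744, 0.069350927593711, 0.777493219314767, 0.444693317871744, -0.444693317871744, 0.069350927593711, -0.777493219314767, -0.444693317871744, 0.444693317871744, 0.069350927593711, -0.777493219314767, 0.444693317871744, -0.444693317871744, 0.069350927593711, 0.777493219314767, -0.444693317871744, -0.444693317871744, 0.069350927593711, -0.777493219314767, -0.444693317871744, -0.444693317871744, 0.069350927593711, 0.129933544765007, 0.129933544765007, 0.982972302707253, 0.0516072821665132, -0.129933544765007, 0.129933544765007, 0.982972302707253, 0.0516072821665132, 0.129933544765007, -0.129933544765007, 0.982972302707253, 0.0516072821665132, 0.129933544765007, 0.129933544765007, -0.982972302707253, 0.0516072821665132, -0.129933544765007, -0.129933544765007, 0.982972302707253, 0.0516072821665132, -0.129933544765007, 0.129933544765007, -0.982972302707253, 0.0516072821665132, 0.129933544765007, -0.129933544765007, -0.982972302707253, 0.0516072821665132, -0.129933544765007, -0.129933544765007, -0.982972302707253, 0.0516072821665132, -0.129933544765007, 0.982972302707253, 0.129933544765007, 0.0516072821665132, 0.129933544765007, -0.982972302707253, 0.129933544765007, 0.0516072821665132, 0.129933544765007, 0.982972302707253, -0.129933544765007, 0.0516072821665132, -0.129933544765007, -0.982972302707253, 0.129933544765007, 0.0516072821665132, -0.129933544765007, 0.982972302707253, -0.129933544765007, 0.0516072821665132, 0.129933544765007, -0.982972302707253, -0.129933544765007, 0.0516072821665132, -0.129933544765007, -0.982972302707253, -0.129933544765007, 0.0516072821665132, 0.129933544765007, 0.982972302707253, 0.129933544765007, 0.0516072821665132, 0.982972302707253, 0.129933544765007, 0.129933544765007, 0.0516072821665132, -0.982972302707253, 0.129933544765007, 0.129933544765007, 0.0516072821665132, 0.982972302707253, -0.129933544765007, 0.129933544765007, 0.0516072821665132, 0.982972302707253, 0.129933544765007, -0.129933544765007, 0.0516072821665132, -0.982972302707253, -0.129933544765007, 0.129933544765007, 0.0516072821665132, -0.982972302707253, 0.129933544765007, -0.129933544765007, 0.0516072821665132, 0.982972302707253, -0.129933544765007, -0.129933544765007, 0.0516072821665132, -0.982972302707253, -0.129933544765007, -0.129933544765007, 0.0516072821665132, 0.345770219761128, 0.938319218137592, 0, 0.0634833699346416, -0.345770219761128, 0.938319218137592, 0, 0.0634833699346416, 0.345770219761128, -0.938319218137592, 0, 0.0634833699346416, -0.345770219761128, -0.938319218137592, 0, 0.0634833699346416, 0.938319218137592, 0.345770219761128, 0, 0.0634833699346416, -0.938319218137592, 0.345770219761128, 0, 0.0634833699346416, 0.938319218137592, -0.345770219761128, 0, 0.0634833699346416, -0.938319218137592, -0.345770219761128, 0, 0.0634833699346416, 0.345770219761128, 0, 0.938319218137592, 0.0634833699346416, -0.345770219761128, 0, 0.938319218137592, 0.0634833699346416, 0.345770219761128, 0, -0.938319218137592, 0.0634833699346416, -0.345770219761128, 0, -0.938319218137592, 0.0634833699346416, 0.938319218137592, 0, 0.345770219761128, 0.0634833699346416, -0.938319218137592, 0, 0.345770219761128, 0.0634833699346416, 0.938319218137592, 0, -0.345770219761128, 0.0634833699346416, -0.938319218137592, 0, -0.345770219761128, 0.0634833699346416, 0, 0.345770219761128, 0.938319218137592, 0.0634833699346416, 0, -0.345770219761128, 0.938319218137592, 0.0634833699346416, 0, 0.345770219761128, -0.938319218137592, 0.0634833699346416, 0, -0.345770219761128, -0.938319218137592, 0.0634833699346416, 0, 0.938319218137592, 0.345770219761128, 0.0634833699346416, 0, -0.938319218137592, 0.345770219761128, 0.0634833699346416, 0, 0.938319218137592, -0.345770219761128, 0.0634833699346416, 0, -0.938319218137592, -0.345770219761128, 0.0634833699346416, 0.159041710538353, 0.836036015482459, 0.525118572443642, 0.0694951574710432, -0.159041710538353, 0.836036015482459, 0.525118572443642, 0.0694951574710432, 0.159041710538353, -0.836036015482459, 0.525118572443642, 0.0694951574710432, 0.159041710538353, 0.836036015482459, -0.525118572443642, 0.0694951574710432, -0.159041710538353, -0.836036015482459, 0.525118572443642, 0.0694951574710432, 0.159041710538353, -0.836036015482459, -0.525118572443642, 0.0694951574710432, -0.159041710538353, 0.836036015482459, -0.525118572443642, 0.0694951574710432, -0.159041710538353, -0.836036015482459, -0.525118572443642, 0.0694951574710432, 0.836036015482459, 0.159041710538353, 0.525118572443642, 0.0694951574710432, -0.836036015482459, 0.159041710538353, 0.525118572443642, 0.0694951574710432, 0.836036015482459, -0.159041710538353, 0.525118572443642, 0.0694951574710432, 0.836036015482459, 0.159041710538353, -0.525118572443642, 0.0694951574710432, -0.836036015482459, -0.159041710538353, 0.525118572443642, 0.0694951574710432, 0.836036015482459, -0.159041710538353, -0.525118572443642, 0.0694951574710432, -0.836036015482459, 0.159041710538353, -0.525118572443642, 0.0694951574710432, -0.836036015482459, -0.159041710538353, -0.525118572443642, 0.0694951574710432, 0.525118572443642, 0.159041710538353, 0.836036015482459, 0.0694951574710432, -0.525118572443642, 0.159041710538353, 0.836036015482459, 0.0694951574710432, 0.525118572443642, -0.159041710538353, 0.836036015482459, 0.0694951574710432, 0.525118572443642, 0.159041710538353, -0.836036015482459, 0.0694951574710432, -0.525118572443642, -0.159041710538353, 0.836036015482459, 0.0694951574710432, 0.525118572443642, -0.159041710538353, -0.836036015482459, 0.0694951574710432, -0.525118572443642, 0.159041710538353, -0.836036015482459, 0.0694951574710432, -0.525118572443642, -0.159041710538353, -0.836036015482459, 0.0694951574710432, 0.525118572443642, 0.836036015482459, 0.159041710538353, 0.0694951574710432, -0.525118572443642, 0.836036015482459, 0.159041710538353, 0.0694951574710432, 0.525118572443642, -0.836036015482459, 0.159041710538353, 0.0694951574710432, 0.525118572443642, 0.836036015482459, -0.159041710538353, 0.0694951574710432, -0.525118572443642, -0.836036015482459, 0.159041710538353, 0.0694951574710432, 0.525118572443642, -0.836036015482459, -0.159041710538353, 0.0694951574710432, -0.525118572443642, 0.836036015482459, -0.159041710538353, 0.0694951574710432, -0.525118572443642, -0.836036015482459, -0.159041710538353, 0.0694951574710432, 0.159041710538353, 0.525118572443642, 0.836036015482459, 0.0694951574710432, -0.159041710538353, 0.525118572443642, 0.836036015482459, 0.0694951574710432, 0.159041710538353, -0.525118572443642, 0.836036015482459, 0.0694951574710432, 0.159041710538353, 0.525118572443642, -0.836036015482459, 0.0694951574710432, -0.159041710538353, -0.525118572443642, 0.836036015482459, 0.0694951574710432, 0.159041710538353, -0.525118572443642, -0.836036015482459, 0.0694951574710432, -0.159041710538353, 0.525118572443642, -0.836036015482459, 0.0694951574710432, -0.159041710538353, -0.525118572443642, -0.836036015482459, 0.0694951574710432, 0.836036015482459, 0.525118572443642, 0.159041710538353, 0.0694951574710432, -0.836036015482459, 0.525118572443642, 0.159041710538353, 0.0694951574710432, 0.836036015482459, -0.525118572443642, 0.159041710538353, 0.0694951574710432, 0.836036015482459, 0.525118572443642, -0.159041710538353, 0.0694951574710432, -0.836036015482459, -0.525118572443642, 0.159041710538353, 0.0694951574710432, 0.836036015482459, -0.525118572443642, -0.159041710538353, 0.0694951574710432, -0.836036015482459, 0.525118572443642, -0.159041710538353, 0.0694951574710432, -0.836036015482459, -0.525118572443642, -0.159041710538353, 0.0694951574710432), ncol = 4L, byrow = TRUE)
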