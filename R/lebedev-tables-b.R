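# Lebedev-Laikov angular quadrature point sets (unit sphere).
# Auto-generated tables; columns x, y, z, w with sum(w) = 4*pi.
.lebedev_tables[["302"]] <- matrix(c(1, 0, 0, 0.0107391093975558, -1, 0, 0, 0.0107391093975558, 0, 1, 0, 0.0107391093975558, 0, -1, 0, 0.0107391093975558, 0, 0, 1, 0.0107391093975558, 0, 0, -1, 0.0107391093975558, 0.577350269189626, 0.577350269189626, 0.577350269189626, 0.0452278668209187, -0.577350269189626, 0.577350269189626, 0.577350269189626, 0.0452278668209187, 0.577350269189626, -0.577350269189626, 0.577350269189626, 0.0452278668209187, 0.577350269189626, 0.577350269189626, -0.577350269189626, 0.0452278668209187, -0.577350269189626, -0.577350269189626, 0.577350269189626, 0.0452278668209187, 0.577350269189626, -0.577350269189626, -0.577350269189626, 0.0452278668209187, -0.577350269189626, 0.577350269189626, -0.577350269189626, 0.0452278668209187, -0.577350269189626, -0.577350269189626, -0.577350269189626, 0.0452278668209187, 0.351564034557011, 0.351564034557011, 0.867643624544083, 0.0433513198809539, -0.351564034557011, 0.351564034557011, 0.867643624544083, 0.0433513198809539, 0.351564034557011, -0.351564034557011, 0.867643624544083, 0.0433513198809539, 0.351564034557011, 0.351564034557011, -0.867643624544083, 0.0433513198809539, -0.351564034557011, -0.351564034557011, 0.867643624544083, 0.0433513198809539, -0.351564034557011, 0.351564034557011, -0.867643624544083, 0.0433513198809539, 0.351564034557011, -0.351564034557011, -0.867643624544083, 0.0433513198809539, -0.351564034557011, -0.351564034557011, -0.867643624544083, 0.0433513198809539, -0.351564034557011, 0.867643624544083, 0.351564034557011, 0.0433513198809539, 0.351564034557011, -0.867643624544083, 0.351564034557011, 0.0433513198809539, 0.351564034557011, 0.867643624544083, -0.351564034557011, 0.0433513198809539, -0.351564034557011, -0.867643624544083, 0.351564034557011, 0.0433513198809539, -0.351564034557011, 0.867643624544083, -0.351564034557011, 0.0433513198809539, 0.351564034557011, -0.867643624544083, -0.351564034557011, 0.0433513198809539, -0.351564034557011, -0.867643624544083, -0.351564034557011, 0.0433513198809539, 0.351564034557011, 0.867643624544083, 0.351564034557011, 0.0433513198809539, 0.867643624544083, 0.351564034557011, 0.351564034557011, 0.0433513198809539, -0.867643624544083, 0.351564034557011, 0.351564034557011, 0.0433513198809539, 0.867643624544083, -0.351564034557011, 0.351564034557011, 0.0433513198809539, 0.867643624544083, 0.351564034557011, -0.351564034557011, 0.0433513198809539, -0.867643624544083, -0.351564034557011, 0.351564034557011, 0.0433513198809539, -0.867643624544083, 0.351564034557011, -0.351564034557011, 0.0433513198809539, 0.867643624544083, -0.351564034557011, -0.351564034557011, 0.0433513198809539, -0.867643624544083, -0.351564034557011, -0.351564034557011, 0.0433513198809539, 0.656632941021961, 0.656632941021961, 0.371034178384821, 0.0452995368084606, -0.656632941021961, 0.656632941021961, 0.371034178384821, 0.0452995368084606, 0.656632941021961, -0.656632941021961, 0.371034178384821, 0.0452995368084606, 0.656632941021961, 0.656632941021961, -0.371034178384821, 0.0452995368084606, -0.656632941021961, -0.656632941021961, 0.371034178384821, 0.0452995368084606, -0.656632941021961, 0.656632941021961, -0.371034178384821, 0.0452995368084606, 0.656632941021961, -0.656632941021961, -0.371034178384821, 0.0452995368084606, -0.656632941021961, -0.656632941021961, -0.371034178384821, 0.0452995368084606, -0.656632941021961, 0.371034178384821, 0.656632941021961, 0.0452995368084606, 0.656632941021961, -0.371034178384821, 0.656632941021961, 0.0452995368084606, 0.656632941021961, 0.371034178384821, -0.656632941021961, 0.0452995368084606, -0.656632941021961, -0.371034178384821, 0.656632941021961, 0.0452995368084606, -0.656632941021961, 0.371034178384821, -0.656632941021961, 0.0452995368084606, 0.656632941021961, -0.371034178384821, -0.656632941021961, 0.0452995368084606, -0.656632941021961, -0.371034178384821, -0.656632941021961, 0.0452995368084606, 0.656632941021961, 0.371034178384821, 0.656632941021961, 0.0452995368084606, 0.371034178384821, 0.656632941021961, 0.656632941021961, 0.0452995368084606, -0.371034178384821, 0.656632941021961, 0.656632941021961, 0.0452995368084606, 0.371034178384821, -0.656632941021961, 0.656632941021961, 0.0452995368084606, 0.371034178384821, 0.656632941021961, -0.656632941021961, 0.0452995368084606, -0.371034178384821, -0.656632941021961, 0.656632941021961, 0.0452995368084606, -0.371034178384821, 0.656632941021961, -0.656632941021961, 0.0452995368084606, 0.371034178384821, -0.656632941021961, -0.656632941021961, 0.0452995368084606, -0.371034178384821, -0.656632941021961, -0.656632941021961, 0.0452995368084606, 0.4729054132581, 0.4729054132581, 0.743452042987556, 0.0449465105168387, -0.4729054132581, 0.4729054132581, 0.743452042987556, 0.0449465105168387, 0.4729054132581, -0.4729054132581, 0.743452042987556, 0.0449465105168387, 0.4729054132581, 0.4729054132581, -0.743452042987556, 0.0449465105168387, -0.4729054132581, -0.4729054132581, 0.743452042987556, 0.0449465105168387, -0.4729054132581, 0.4729054132581, -0.743452042987556, 0.0449465105168387, 0.4729054132581, -0.4729054132581, -0.743452042987556, 0.0449465105168387, -0.4729054132581, -0.4729054132581, -0.743452042987556, 0.0449465105168387, -0.4729054132581, 0.743452042987556, 0.4729054132581, 0.0449465105168387, 0.4729054132581, -0.743452042987556, 0.4729054132581, 0.0449465105168387, 0.4729054132581, 0.743452042987556, -0.4729054132581, 0.0449465105168387, -0.4729054132581, -0.743452042987556, 0.4729054132581, 0.0449465105168387, -0.4729054132581, 0.743452042987556, -0.4729054132581, 0.0449465105168387, 0.4729054132581, -0.743452042987556, -0.4729054132581, 0.0449465105168387, -0.4729054132581, -0.743452042987556, -0.4729054132581, 0.0449465105168387, 0.4729054132581, 0.743452042987556, 0.4729054132581, 0.0449465105168387, 0.743452042987556, 0.4729054132581, 0.4729054132581, 0.0449465105168387, -0.743452042987556, 0.4729054132581, 0.4729054132581, 0.0449465105168387, 0.743452042987556, -0.4729054132581, 0.4729054132581, 0.0449465105168387, 0.743452042987556, 0.4729054132581, -0.4729054132581, 0.0449465105168387, -0.743452042987556, -0.4729054132581, 0.4729054132581, 0.0449465105168387, -0.743452042987556, 0.4729054132581, -0.4729054132581, 0.0449465105168387, 0.743452042987556, -0.4729054132581, -0.4729054132581, 0.0449465105168387, -0.743452042987556, -0.4729054132581, -0.4729054132581, 0.0449465105168387, 0.0961830852261478, 0.0961830852261478, 0.990705621379408, 0.0295573780869762, -0.0961830852261478, 0.0961830852261478, 0.990705621379408, 0.0295573780869762, 0.0961830852261478, -0.0961830852261478, 0.990705621379408, 0.0295573780869762, 0.0961830852261478, 0.0961830852261478, -0.990705621379408, 0.0295573780869762, -0.0961830852261478, -0.0961830852261478, 0.990705621379408, 0.0295573780869762, -0.0961830852261478, 0.0961830852261478, -0.990705621379408, 0.0295573780869762, 0.0961830852261478, -0.0961830852261478, -0.990705621379408, 0.0295573780869762, -0.0961830852261478, -0.0961830852261478, -0.990705621379408, 0.0295573780869762, -0.0961830852261478, 0.990705621379408, 0.0961830852261478, 0.0295573780869762, 0.0961830852261478, -0.990705621379408, 0.0961830852261478, 0.0295573780869762, 0.0961830852261478, 0.990705621379408, -0.0961830852261478, 0.0295573780869762, -0.0961830852261478, -0.990705621379408, 0.0961830852261478, 0.0295573780869762, -0.0961830852261478, 0.990705621379408, -0.0961830852261478, 0.0295573780869762, 0.0961830852261478, -0.990705621379408, -0.0961830852261478, 0.0295573780869762, -0.0961830852261478, -0.990705621379408, -0.0961830852261478, 0.0295573780869762, 0.0961830852261478, 0.990705621379408, 0.0961830852261478, 0.0295573780869762, 0.990705621379408, 0.0961830852261478, 0.0961830852261478, 0.0295573780869762, -0.990705621379408, 0.0961830852261478, 0.0961830852261478, 0.0295573780869762, 0.990705621379408, -0.0961830852261478, 0.0961830852261478, 0.0295573780869762, 0.990705621379408, 0.0961830852261478, -0.0961830852261478, 0.0295573780869762, -0.990705621379408, -0.0961830852261478, 0.0961830852261478, 0.0295573780869762, -0.990705621379408, 0.0961830852261478, -0.0961830852261478, 0.0295573780869762, 0.990705621379408, -0.0961830852261478, -0.0961830852261478, 0.0295573780869762, -0.990705621379408, -0.0961830852261478, -0.0961830852261478, 0.0295573780869762, 0.221964523629418, 0.221964523629418, 0.949454317226443, 0.0390682571589194, -0.221964523629418, 0.221964523629418, 0.949454317226443, 0.0390682571589194, 0.221964523629418, -0.221964523629418, 0.949454317226443, 0.0390682571589194, 0.221964523629418, 0.221964523629418, -0.949454317226443, 0.0390682571589194, -0.221964523629418, -0.221964523629418, 0.949454317226443, 0.0390682571589194, -0.221964523629418, 0.221964523629418, -0.949454317226443, 0.0390682571589194, 0.221964523629418, -0.221964523629418, -0.949454317226443, 0.0390682571589194, -0.221964523629418, -0.221964523629418, -0.949454317226443, 0.0390682571589194, -0.221964523629418, 0.949454317226443, 0.221964523629418, 0.0390682571589194, 0.221964523629418, -0.949454317226443, 0.221964523629418, 0.0390682571589194, 0.221964523629418, 0.949454317226443, -0.221964523629418, 0.0390682571589194, -0.221964523629418, -0.949454317226443, 0.221964523629418, 0.0390682571589194, -0.221964523629418, 0.949454317226443, -0.221964523629418, 0.0390682571589194, 0.221964523629418, -0.949454317226443, -0.221964523629418, 0.0390682571589194, -0.221964523629418, -0.949454317226443, -0.221964523629418, 0.0390682571589194, 0.221964523629418, 0.949454317226443, 0.221964523629418, 0.0390682571589194, 0.949454317226443, 0.221964523629418, 0.221964523629418, 0.0390682571589194, -0.949454317226443, 0.221964523629418, 0.221964523629418, 0.0390682571589194, 0.949454317226443, -0.221964523629418, 0.221964523629418, 0.0390682571589194, 0.949454317226443, 0.221964523629418, -0.221964523629418, 0.0390682571589194, -0.949454317226443, -0.221964523629418, 0.221964523629418, 0.0390682571589194, -0.949454317226443, 0.221964523629418, -0.221964523629418, 0.0390682571589194, 0.949454317226443, -0.221964523629418, -0.221964523629418, 0.0390682571589194, -0.949454317226443, -0.221964523629418, -0.221964523629418, 0.0390682571589194, 0.701176641608955, 0.701176641608955, 0.129238672710514, 0.0458678283786604, -0.701176641608955, 0.701176641608955, 0.129238672710514, 0.0458678283786604, 0.701176641608955, -0.701176641608955, 0.129238672710514, 0.0458678283786604, 0.701176641608955, 0.701176641608955, -0.129238672710514, 0.0458678283786604, -0.701176641608955, -0.701176641608955, 0.129238672710514, 0.0458678283786604, -0.701176641608955, 0.701176641608955, -0.129238672710514, 0.0458678283786604, 0.701176641608955, -0.701176641608955, -0.129238672710514, 0.0458678283786604, -0.701176641608955, -0.701176641608955, -0.129238672710514, 0.0458678283786604, -0.701176641608955, 0.129238672710514, 0.701176641608955, 0.0458678283786604, 0.701176641608955, -0.129238672710514, 0.701176641608955, 0.0458678283786604, 0.701176641608955, 0.129238672710514, -0.701176641608955, 0.0458678283786604, -0.701176641608955, -0.129238672710514, 0.701176641608955, 0.0458678283786604, -0.701176641608955, 0.129238672710514, -0.701176641608955, 0.0458678283786604, 0.701176641608955, -0.129238672710514, -0.701176641608955, 0.0458678283786604, -0.701176641608955, -0.129238672710514, -0.701176641608955, 0.0458678283786604, 0.701176641608955, 0.129238672710514, 0.701176641608955, 0.0458678283786604, 0.129238672710514, 0.701176641608955, 0.701176641608955, 0.0458678283786604, -0.129238672710514, 0.701176641608955, 0.701176641608955, 0.0458678283786604, 0.129238672710514, -0.701176641608955, 0.701176641608955, 0.0458678283786604, 0.129238672710514, 0.701176641608955, -0.701176641608955, 0.0458678283786604, -0.129238672710514, -0.701176641608955, 0.701176641608955, 0.0458678283786604, -0.129238672710514, 0.701176641608955, -0.701176641608955, 0.0458678283786604, 0.129238672710514, -0.701176641608955, -0.701176641608955, 0.0458678283786604, -0.129238672710514, -0.701176641608955, -0.701176641608955, 0.0458678283786604, 0.264415288706066, 0.964408914879206, 0, 0.0374772521070842, -0.264415288706066, 0.964408914879206, 0, 0.0374772521070842, 0.264415288706066, -0.964408914879206, 0, 0.0374772521070842, -0.264415288706066, -0.964408914879206, 0, 0.0374772521070842, 0.964408914879206, 0.264415288706066, 0, 0.0374772521070842, -0.964408914879206, 0.264415288706066, 0, 0.0374772521070842, 0.964408914879206, -0.264415288706066, 0, 0.0374772521070842, -0.964408914879206, -0.264415288706066, 0, 0.0374772521070842, 0.264415288706066, 0, 0.964408914879206, 0.0374772521070842, -0.264415288706066, 0, 0.964408914879206, 0.0374772521070842, 0.264415288706066, 0, -0.964408914879206, 0.0374772521070842, -0.264415288706066, 0, -0.964408914879206, 0.0374772521070842, 0.964408914879206, 0, 0.264415288706066, 0.0374772521070842, -0.964408914879206, 0, 0.264415288706066, 0.0374772521070842, 0.964408914879206, 0, -0.264415288706066, 0.0374772521070842, -0.964408914879206, 0, -0.264415288706066, 0.0374772521070842, 0, 0.264415288706066, 0.964408914879206, 0.0374772521070842, 0, -0.264415288706066, 0.964408914879206, 0.0374772521070842, 0, 0.264415288706066, -0.964408914879206, 0.0374772521070842, 0, -0.264415288706066, -0.964408914879206, 0.0374772521070842, 0, 0.964408914879206, 0.264415288706066, 0.0374772521070842, 0, -0.964408914879206, 0.264415288706066, 0.0374772521070842, 0, 0.964408914879206, -0.264415288706066, 0.0374772521070842, 0, -0.964408914879206, -0.264415288706066, 0.0374772521070842, 0.571895589187896, 0.820326419827759, 0, 0.0452492503501743, -0.571895589187896, 0.820326419827759, 0, 0.0452492503501743, 0.571895589187896, -0.820326419827759, 0, 0.0452492503501743, -0.571895589187896, -0.820326419827759, 0, 0.0452492503501743, 0.820326419827759, 0.571895589187896, 0, 0.0452492503501743, -0.820326419827759, 0.571895589187896, 0, 0.0452492503501743, 0.820326419827759, -0.571895589187896, 0, 0.0452492503501743, -0.820326419827759, -0.571895589187896, 0, 0.0452492503501743, 0.571895589187896, 0, 0.820326419827759, 0.0452492503501743, -0.571895589187896, 0, 0.820326419827759, 0.0452492503501743, 0.571895589187896, 0, -0.820326419827759, 0.0452492503501743, -0.571895589187896, 0, -0.820326419827759, 0.0452492503501743, 0.820326419827759, 0, 0.571895589187896, 0.0452492503501743, -0.820326419827759, 0, 0.571895589187896, 0.0452492503501743, 0.820326419827759, 0, -0.571895589187896, 0.0452492503501743, -0.820326419827759, 0, -0.571895589187896, 0.0452492503501743, 0, 0.571895589187896, 0.820326419827759, 0.0452492503501743, 0, -0.571895589187896, 0.820326419827759, 0.0452492503501743, 0, 0.571895589187896, -0.820326419827759, 0.0452492503501743, 0, -0.571895589187896, -0.820326419827759, 0.0452492503501743, 0, 0.820326419827759, 0.571895589187896, 0.0452492503501743, 0, -0.820326419827759, 0.571895589187896, 0.0452492503501743, 0, 0.820326419827759, -0.571895589187896, 0.0452492503501743, 0, -0.820326419827759, -0.571895589187896, 0.0452492503501743, 0.251003475177047, 0.800072749407395, 0.544867737258077, 0.0448813022692132, -0.251003475177047, 0.800072749407395, 0.544867737258077, 0.0448813022692132, 0.251003475177047, -0.800072749407395, 0.544867737258077, 0.0448813022692132, 0.251003475177047, 0.800072749407395, -0.544867737258077, 0.0448813022692132, -0.251003475177047, -0.800072749407395, 0.544867737258077, 0.0448813022692132, 0.251003475177047, -0.800072749407395, -0.544867737258077, 0.0448813022692132, -0.251003475177047, 0.800072749407395, -0.544867737258077, 0.0448813022692132, -0.251003475177047, -0.800072749407395, -0.544867737258077, 0.0448813022692132, 0.800072749407395, 0.251003475177047, 0.544867737258077, 0.0448813022692132, -0.800072749407395, 0.251003475177047, 0.544867737258077, 0.0448813022692132, 0.800072749407395, -0.251003475177047, 0.544867737258077, 0.0448813022692132, 0.800072749407395, 0.251003475177047, -0.544867737258077, 0.0448813022692132, -0.800072749407395, -0.251003475177047, 0.544867737258077, 0.0448813022692132, 0.800072749407395, -0.251003475177047, -0.544867737258077, 0.0448813022692132, -0.800072749407395, 0.251003475177047, -0.544867737258077, 0.0448813022692132, -0.800072749407395, -0.251003475177047, -0.544867737258077, 0.0448813022692132, 0.544867737258077, 0.251003475177047, 0.800072749407395, 0.0448813022692132, -0.544867737258077, 0.251003475177047, 0.800072749407395, 0.0448813022692132, 0.544867737258077, -0.251003475177047, 0.800072749407395, 0.0448813022692132, 0.544867737258077, 0.251003475177047, -0.800072749407395, 0.0448813022692132, -0.544867737258077, -0.251003475177047, 0.800072749407395, 0.0448813022692132, 0.544867737258077, -0.251003475177047, -0.800072749407395, 0.0448813022692132, -0.544867737258077, 0.251003475177047, -0.800072749407395, 0.0448813022692132, -0.544867737258077, -0.251003475177047, -0.800072749407395, 0.0448813022692132, 0.544867737258077, 0.800072749407395, 0.251003475177047, 0.0448813022692132, -0.544867737258077, 0.800072749407395, 0.251003475177047, 0.0448813022692132, 0.544867737258077, -0.800072749407395, 0.251003475177047, 0.0448813022692132, 0.544867737258077, 0.800072749407395, -0.251003475177047, 0.0448813022692132, -0.544867737258077, -0.800072749407395, 0.251003475177047, 0.0448813022692132, 0.544867737258077, -0.800072749407395, -0.251003475177047, 0.0448813022692132, -0.544867737258077, 0.800072749407395, -0.251003475177047, 0.0448813022692132, -0.544867737258077, -0.800072749407395, -0.251003475177047, 0.0448813022692132, 0.251003475177047, 0.544867737258077, 0.800072749407395, 0.0448813022692132, -0.251003475177047, 0.544867737258077, 0.800072749407395, 0.0448813022692132, 0.251003475177047, -0.544867737258077, 0.800072749407395, 0.0448813022692132, 0.251003475177047, 0.544867737258077, -0.800072749407395, 0.0448813022692132, -0.251003475177047, -0.544867737258077, 0.800072749407395, 0.0448813022692132, 0.251003475177047, -0.544867737258077, -0.800072749407395, 0.0448813022692132, -0.251003475177047, 0.544867737258077, -0.800072749407395, 0.0448813022692132, -0.251003475177047, -0.544867737258077, -0.800072749407395, 0.0448813022692132, 0.800072749407395, 0.544867737258077, 0.251003475177047, 0.0448813022692132, -0.800072749407395, 0.544867737258077, 0.251003475177047, 0.0448813022692132, 0.800072749407395, -0.544867737258077, 0.251003475177047, 0.0448813022692132, 0.800072749407395, 0.544867737258077, -0.251003475177047, 0.0448813022692132, -0.800072749407395, -0.544867737258077, 0.251003475177047, 0.0448813022692132, 0.800072749407395, -0.544867737258077, -0.251003475177047, 0.0448813022692132, -0.800072749407395, 0.544867737258077, -0.251003475177047, 0.0448813022692132, -0.800072749407395, -0.544867737258077, -0.251003475177047, 0.0448813022692132, 0.123354853258333, 0.412772408316853, 0.902442529533, 0.0426290524077215, -0.123354853258333, 0.412772408316853, 0.902442529533, 0.0426290524077215, 0.123354853258333, -0.412772408316853, 0.902442529533, 0.0426290524077215, 0.123354853258333, 0.412772408316853, -0.902442529533, 0.0426290524077215, -0.123354853258333, -0.412772408316853, 0.902442529533, 0.0426290524077215, 0.123354853258333, -0.412772408316853, -0.902442529533, 0.0426290524077215, -0.123354853258333, 0.412772408316853, -0.902442529533, 0.0426290524077215, -0.123354853258333, -0.412772408316853, -0.902442529533, 0.0426290524077215, 0.412772408316853, 0.123354853258333, 0.902442529533, 0.0426290524077215, -0.412772408316853, 0.123354853258333, 0.902442529533, 0.0426290524077215, 0.412772408316853, -0.123354853258333, 0.902442529533, 0.0426290524077215, 0.412772408316853, 0.123354853258333, -0.902442529533, 0.0426290524077215, -0.412772408316853, -0.123354853258333, 0.902442529533, 0.0426290524077215, 0.412772408316853, -0.123354853258333, -0.902442529533, 0.0426290524077215, -0.412772408316853, 0.123354853258333, -0.902442529533, 0.0426290524077215, -0.412772408316853, -0.123354853258333, -0.902442529533, 0.0426290524077215, 0.902442529533, 0.123354853258333, 0.412772408316853, 0.0426290524077215, -0.902442529533, 0.123354853258333, 0.412772408316853, 0.0426290524077215, 0.902442529533, -0.123354853258333, 0.412772408316853, 0.0426290524077215, 0.902442529533, 0.123354853258333, -0.412772408316853, 0.0426290524077215, -0.902442529533, -0.123354853258333, 0.412772408316853, 0.0426290524077215, 0.902442529533, -0.123354853258333, -0.412772408316853, 0.0426290524077215, -0.902442529533, 0.123354853258333, -0.412772408316853, 0.0426290524077215, -0.902442529533, -0.123354853258333, -0.412772408316853, 0.0426290524077215, 0.902442529533, 0.412772408316853, 0.123354853258333, 0.0426290524077215, -0.902442529533, 0.412772408316853, 0.123354853258333, 0.0426290524077215, 0.902442529533, -0.412772408316853, 0.123354853258333, 0.0426290524077215, 0.902442529533, 0.412772408316853, -0.123354853258333, 0.0426290524077215, -0.902442529533, -0.412772408316853, 0.123354853258333, 0.0426290524077215, 0.902442529533, -0.412772408316853, -0.123354853258333, 0.0426290524077215, -0.902442529533, 0.412772408316853, -0.123354853258333, 0.0426290524077215, -0.902442529533, -0.412772408316853, -0.123354853258333, 0.0426290524077215, 0.123354853258333, 0.902442529533, 0.412772408316853, 0.0426290524077215, -0.123354853258333, 0.902442529533, 0.412772408316853, 0.0426290524077215, 0.123354853258333, -0.902442529533, 0.412772408316853, 0.0426290524077215, 0.123354853258333, 0.902442529533, -0.412772408316853, 0.0426290524077215, -0.123354853258333, -0.902442529533, 0.412772408316853, 0.0426290524077215, 0.123354853258333, -0.902442529533, -0.412772408316853, 0.0426290524077215, -0.123354853258333, 0.902442529533, -0.412772408316853, 0.0426290524077215, -0.123354853258333, -0.902442529533, -0.412772408316853, 0.0426290524077215, 0.412772408316853, 0.902442529533, 0.123354853258333, 0.0426290524077215, -0.412772408316853, 0.902442529533, 0.123354853258333, 0.0426290524077215, 0.412772408316853, -0.902442529533, 0.123354853258333, 0.0426290524077215, 0.412772408316853, 0.902442529533, -0.123354853258333, 0.0426290524077215, -0.412772408316853, -0.902442529533, 0.123354853258333, 0.0426290524077215, 0.412772408316853, -0.902442529533, -0.123354853258333, 0.0426290524077215, -0.412772408316853, 0.902442529533, -0.123354853258333, 0.0426290524077215, -0.412772408316853, -0.902442529533, -0.123354853258333, 0.0426290524077215), ncol = 4L, byrow = TRUE)
.lebedev_tables[["434"]] <- matrix(c(1, 0, 0, 0.00661732254861092, -1, 0, 0, 0.00661732254861092, 0, 1, 0, 0.00661732254861092, 0, -1, 0, 0.00661732254861092, 0, 0, 1, 0.00661732254861092, 0, 0, -1, 0.00661732254861092, 0, 0.707106781186548, 0.707106781186548, 0.0320218765750967, 0, -0.707106781186548, 0.707106781186548, 0.0320218765750967, 0, 0.707106781186548, -0.707106781186548, 0.0320218765750967, 0, -0.707106781186548, -0.707106781186548, 0.0320218765750967, 0.707106781186548, 0, 0.707106781186548, 0.0320218765750967, 0.707106781186548, 0, -0.707106781186548, 0.0320218765750967, -0.707106781186548, 0, 0.707106781186548, 0.0320218765750967, -0.707106781186548, 0, -0.707106781186548, 0.0320218765750967, 0.707106781186548, 0.707106781186548, 0, 0.0320218765750967, -0.707106781186548, 0.707106781186548, 0, 0.0320218765750967, 0.707106781186548, -0.707106781186548, 0, 0.0320218765750967, -0.707106781186548, -0.707106781186548, 0, 0.0320218765750967, 0.577350269189626, 0.577350269189626, 0.577350269189626, 0.0315707117871508, -0.577350269189626, 0.577350269189626, 0.577350269189626, 0.0315707117871508, 0.577350269189626, -0.577350269189626, 0.577350269189626, 0.0315707117871508, 0.577350269189626, 0.577350269189626, -0.577350269189626, 0.0315707117871508, -0.577350269189626, -0.577350269189626, 0.577350269189626, 0.0315707117871508, 0.577350269189626, -0.577350269189626, -0.577350269189626, 0.0315707117871508, -0.577350269189626, 0.577350269189626, -0.577350269189626, 0.0315707117871508, -0.577350269189626, -0.577350269189626, -0.577350269189626, 0.0315707117871508, 0.690934630750911, 0.690934630750911, 0.212646824707552, 0.031797991969691, -0.690934630750911, 0.690934630750911, 0.212646824707552, 0.031797991969691, 0.690934630750911, -0.690934630750911, 0.212646824707552, 0.031797991969691, 0.690934630750911, 0.690934630750911, -0.212646824707552, 0.031797991969691, -0.690934630750911, -0.690934630750911, 0.212646824707552, 0.031797991969691, -0.690934630750911, 0.690934630750911, -0.212646824707552, 0.031797991969691, 0.690934630750911, -0.690934630750911, -0.212646824707552, 0.031797991969691, -0.690934630750911, -0.690934630750911, -0.212646824707552, 0.031797991969691, -0.690934630750911, 0.212646824707552, 0.690934630750911, 0.031797991969691, 0.690934630750911, -0.212646824707552, 0.690934630750911, 0.031797991969691, 0.690934630750911, 0.212646824707552, -0.690934630750911, 0.031797991969691, -0.690934630750911, -0.212646824707552, 0.690934630750911, 0.031797991969691, -0.690934630750911, 0.212646824707552, -0.690934630750911, 0.031797991969691, 0.690934630750911, -0.212646824707552, -0.690934630750911, 0.031797991969691, -0.690934630750911, -0.212646824707552, -0.690934630750911, 0.031797991969691, 0.690934630750911, 0.212646824707552, 0.690934630750911, 0.031797991969691, 0.212646824707552, 0.690934630750911, 0.690934630750911, 0.031797991969691, -0.212646824707552, 0.690934630750911, 0.690934630750911, 0.031797991969691, 0.212646824707552, -0.690934630750911, 0.690934630750911, 0.031797991969691, 0.212646824707552, 0.690934630750911, -0.690934630750911, 0.031797991969691, -0.212646824707552, -0.690934630750911, 0.690934630750911, 0.031797991969691, -0.212646824707552, 0.690934630750911, -0.690934630750911, 0.031797991969691, 0.212646824707552, -0.690934630750911, -0.690934630750911, 0.031797991969691, -0.212646824707552, -0.690934630750911, -0.690934630750911, 0.031797991969691, 0.177483605460916, 0.177483605460916, 0.967987158791473, 0.0253121766975908, -0.177483605460916, 0.177483605460916, 0.967987158791473, 0.0253121766975908, 0.177483605460916, -0.177483605460916, 0.967987158791473, 0.0253121766975908, 0.177483605460916, 0.177483605460916, -0.967987158791473, 0.0253121766975908, -0.177483605460916, -0.177483605460916, 0.967987158791473, 0.0253121766975908, -0.177483605460916, 0.177483605460916, -0.967987158791473, 0.0253121766975908, 0.177483605460916, -0.177483605460916, -0.967987158791473, 0.0253121766975908, -0.177483605460916, -0.177483605460916, -0.967987158791473, 0.0253121766975908, -0.177483605460916, 0.967987158791473, 0.177483605460916, 0.0253121766975908, 0.177483605460916, -0.967987158791473, 0.177483605460916, 0.0253121766975908, 0.177483605460916, 0.967987158791473, -0.177483605460916, 0.0253121766975908, -0.177483605460916, -0.967987158791473, 0.177483605460916, 0.0253121766975908, -0.177483605460916, 0.967987158791473, -0.177483605460916, 0.0253121766975908, 0.177483605460916, -0.967987158791473, -0.177483605460916, 0.0253121766975908, -0.177483605460916, -0.967987158791473, -0.177483605460916, 0.0253121766975908, 0.177483605460916, 0.967987158791473, 0.177483605460916, 0.0253121766975908, 0.967987158791473, 0.177483605460916, 0.177483605460916, 0.0253121766975908, -0.967987158791473, 0.177483605460916, 0.177483605460916, 0.0253121766975908, 0.967987158791473, -0.177483605460916, 0.177483605460916, 0.0253121766975908, 0.967987158791473, 0.177483605460916, -0.177483605460916, 0.0253121766975908, -0.967987158791473, -0.177483605460916, 0.177483605460916, 0.0253121766975908, -0.967987158791473, 0.177483605460916, -0.177483605460916, 0.0253121766975908, 0.967987158791473, -0.177483605460916, -0.177483605460916, 0.0253121766975908, -0.967987158791473, -0.177483605460916, -0.177483605460916, 0.0253121766975908, 0.491434263778475, 0.491434263778475, 0.719016501040843, 0.0314376056414214, -0.491434263778475, 0.491434263778475, 0.719016501040843, 0.0314376056414214, 0.491434263778475, -0.491434263778475, 0.719016501040843, 0.0314376056414214, 0.491434263778475, 0.491434263778475, -0.719016501040843, 0.0314376056414214, -0.491434263778475, -0.491434263778475, 0.719016501040843, 0.0314376056414214, -0.491434263778475, 0.491434263778475, -0.719016501040843, 0.0314376056414214, 0.491434263778475, -0.491434263778475, -0.719016501040843, 0.0314376056414214, -0.491434263778475, -0.491434263778475, -0.719016501040843, 0.0314376056414214, -0.491434263778475, 0.719016501040843, 0.491434263778475, 0.0314376056414214, 0.491434263778475, -0.719016501040843, 0.491434263778475, 0.0314376056414214, 0.491434263778475, 0.719016501040843, -0.491434263778475, 0.0314376056414214, -0.491434263778475, -0.719016501040843, 0.491434263778475, 0.0314376056414214, -0.491434263778475, 0.719016501040843, -0.491434263778475, 0.0314376056414214, 0.491434263778475, -0.719016501040843, -0.491434263778475, 0.0314376056414214, -0.491434263778475, -0.719016501040843, -0.491434263778475, 0.0314376056414214, 0.491434263778475, 0.719016501040843, 0.491434263778475, 0.0314376056414214, 0.719016501040843, 0.491434263778475, 0.491434263778475, 0.0314376056414214, -0.719016501040843, 0.491434263778475, 0.491434263778475, 0.0314376056414214, 0.719016501040843, -0.491434263778475, 0.491434263778475, 0.0314376056414214, 0.719016501040843, 0.491434263778475, -0.491434263778475, 0.0314376056414214, -0.719016501040843, -0.491434263778475, 0.491434263778475, 0.0314376056414214, -0.719016501040843, 0.491434263778475, -0.491434263778475, 0.0314376056414214, 0.719016501040843, -0.491434263778475, -0.491434263778475, 0.0314376056414214, -0.719016501040843, -0.491434263778475, -0.491434263778475, 0.0314376056414214, 0.645666470742426, 0.645666470742426, 0.40771266489777, 0.0315826467688963, -0.645666470742426, 0.645666470742426, 0.40771266489777, 0.0315826467688963, 0.645666470742426, -0.645666470742426, 0.40771266489777, 0.0315826467688963, 0.645666470742426, 0.645666470742426, -0.40771266489777, 0.0315826467688963, -0.645666470742426, -0.645666470742426, 0.40771266489777, 0.0315826467688963, -0.645666470742426, 0.645666470742426, -0.40771266489777, 0.0315826467688963, 0.645666470742426, -0.645666470742426, -0.40771266489777, 0.0315826467688963, -0.645666470742426, -0.645666470742426, -0.40771266489777, 0.0315826467688963, -0.645666470742426, 0.40771266489777, 0.645666470742426, 0.0315826467688963, 0.645666470742426, -0.40771266489777, 0.645666470742426, 0.0315826467688963, 0.645666470742426, 0.40771266489777, -0.645666470742426, 0.0315826467688963, -0.645666470742426, -0.40771266489777, 0.645666470742426, 0.0315826467688963, -0.645666470742426, 0.40771266489777, -0.645666470742426, 0.0315826467688963, 0.645666470742426, -0.40771266489777, -0.645666470742426, 0.0315826467688963, -0.645666470742426, -0.40771266489777, -0.645666470742426, 0.0315826467688963, 0.645666470742426, 0.40771266489777, 0.645666470742426, 0.0315826467688963, 0.40771266489777, 0.645666470742426, 0.645666470742426, 0.0315826467688963, -0.40771266489777, 0.645666470742426, 0.645666470742426, 0.0315826467688963, 0.40771266489777, -0.645666470742426, 0.645666470742426, 0.0315826467688963, 0.40771266489777, 0.645666470742426, -0.645666470742426, 0.0315826467688963, -0.40771266489777, -0.645666470742426, 0.645666470742426, 0.0315826467688963, -0.40771266489777, 0.645666470742426, -0.645666470742426, 0.0315826467688963, 0.40771266489777, -0.645666470742426, -0.645666470742426, 0.0315826467688963, -0.40771266489777, -0.645666470742426, -0.645666470742426, 0.0315826467688963, 0.286128901030764, 0.286128901030764, 0.914472801120872, 0.0289365160452208, -0.286128901030764, 0.286128901030764, 0.914472801120872, 0.0289365160452208, 0.286128901030764, -0.286128901030764, 0.914472801120872, 0.0289365160452208, 0.286128901030764, 0.286128901030764, -0.914472801120872, 0.0289365160452208, -0.286128901030764, -0.286128901030764, 0.914472801120872, 0.0289365160452208, -0.286128901030764, 0.286128901030764, -0.914472801120872, 0.0289365160452208, 0.286128901030764, -0.286128901030764, -0.914472801120872, 0.0289365160452208, -0.286128901030764, -0.286128901030764, -0.914472801120872, 0.0289365160452208, -0.286128901030764, 0.914472801120872, 0.286128901030764, 0.0289365160452208, 0.286128901030764, -0.914472801120872, 0.286128901030764, 0.0289365160452208, 0.286128901030764, 0.914472801120872, -0.286128901030764, 0.0289365160452208, -0.286128901030764, -0.914472801120872, 0.286128901030764, 0.0289365160452208, -0.286128901030764, 0.914472801120872, -0.286128901030764, 0.0289365160452208, 0.286128901030764, -0.914472801120872, -0.286128901030764, 0.0289365160452208, -0.286128901030764, -0.914472801120872, -0.286128901030764, 0.0289365160452208, 0.286128901030764, 0.914472801120872, 0.286128901030764, 0.0289365160452208, 0.914472801120872, 0.286128901030764, 0.286128901030764, 0.0289365160452208, -0.914472801120872, 0.286128901030764, 0.286128901030764, 0.0289365160452208, 0.914472801120872, -0.286128901030764, 0.286128901030764, 0.0289365160452208, 0.914472801120872, 0.286128901030764, -0.286128901030764, 0.0289365160452208, -0.914472801120872, -0.286128901030764, 0.286128901030764, 0.0289365160452208, -0.914472801120872, 0.286128901030764, -0.286128901030764, 0.0289365160452208, 0.914472801120872, -0.286128901030764, -0.286128901030764, 0.0289365160452208, -0.914472801120872, -0.286128901030764, -0.286128901030764, 0.0289365160452208, 0.0756808436717802, 0.0756808436717802, 0.994255912631278, 0.0183782620028355, -0.0756808436717802, 0.0756808436717802, 0.994255912631278, 0.0183782620028355, 0.0756808436717802, -0.0756808436717802, 0.994255912631278, 0.0183782620028355, 0.0756808436717802, 0.0756808436717802, -0.994255912631278, 0.0183782620028355, -0.0756808436717802, -0.0756808436717802, 0.994255912631278, 0.0183782620028355, -0.0756808436717802, 0.0756808436717802, -0.994255912631278, 0.0183782620028355, 0.0756808436717802, -0.0756808436717802, -0.994255912631278, 0.0183782620028355, -0.0756808436717802, -0.0756808436717802, -0.994255912631278, 0.0183782620028355, -0.0756808436717802, 0.994255912631278, 0.0756808436717802, 0.0183782620028355, 0.0756808436717802, -0.994255912631278, 0.0756808436717802, 0.0183782620028355, 0.0756808436717802, 0.994255912631278, -0.0756808436717802, 0.0183782620028355, -0.0756808436717802, -0.994255912631278, 0.0756808436717802, 0.0183782620028355, -0.0756808436717802, 0.994255912631278, -0.0756808436717802, 0.0183782620028355, 0.0756808436717802, -0.994255912631278, -0.0756808436717802, 0.0183782620028355, -0.0756808436717802, -0.994255912631278, -0.0756808436717802, 0.0183782620028355, 0.0756808436717802, 0.994255912631278, 0.0756808436717802, 0.0183782620028355, 0.994255912631278, 0.0756808436717802, 0.0756808436717802, 0.0183782620028355, -0.994255912631278, 0.0756808436717802, 0.0756808436717802, 0.0183782620028355, 0.994255912631278, -0.0756808436717802, 0.0756808436717802, 0.0183782620028355, 0.994255912631278, 0.0756808436717802, -0.0756808436717802, 0.0183782620028355, -0.994255912631278, -0.0756808436717802, 0.0756808436717802, 0.0183782620028355, -0.994255912631278, 0.0756808436717802, -0.0756808436717802, 0.0183782620028355, 0.994255912631278, -0.0756808436717802, -0.0756808436717802, 0.0183782620028355, -0.994255912631278, -0.0756808436717802, -0.0756808436717802, 0.0183782620028355, 0.3927259763368, 0.3927259763368, 0.831584400419232, 0.0307294689037843, -0.3927259763368, 0.3927259763368, 0.831584400419232, 0.0307294689037843, 0.3927259763368, -0.3927259763368, 0.831584400419232, 0.0307294689037843, 0.3927259763368, 0.3927259763368, -0.831584400419232, 0.0307294689037843, -0.3927259763368, -0.3927259763368, 0.831584400419232, 0.0307294689037843, -0.3927259763368, 0.3927259763368, -0.831584400419232, 0.0307294689037843, 0.3927259763368, -0.3927259763368, -0.831584400419232, 0.0307294689037843, -0.3927259763368, -0.3927259763368, -0.831584400419232, 0.0307294689037843, -0.3927259763368, 0.831584400419232, 0.3927259763368, 0.0307294689037843, 0.3927259763368, -0.831584400419232, 0.3927259763368, 0.0307294689037843, 0.3927259763368, 0.831584400419232, -0.3927259763368, 0.0307294689037843, -0.3927259763368, -0.831584400419232, 0.3927259763368, 0.0307294689037843, -0.3927259763368, 0.831584400419232, -0.3927259763368, 0.0307294689037843, 0.3927259763368, -0.831584400419232, -0.3927259763368, 0.0307294689037843, -0.3927259763368, -0.831584400419232, -0.3927259763368, 0.0307294689037843, 0.3927259763368, 0.831584400419232, 0.3927259763368, 0.0307294689037843, 0.831584400419232, 0.3927259763368, 0.3927259763368, 0.0307294689037843, -0.831584400419232, 0.3927259763368, 0.3927259763368, 0.0307294689037843, 0.831584400419232, -0.3927259763368, 0.3927259763368, 0.0307294689037843, 0.831584400419232, 0.3927259763368, -0.3927259763368, 0.0307294689037843, -0.831584400419232, -0.3927259763368, 0.3927259763368, 0.0307294689037843, -0.831584400419232, 0.3927259763368, -0.3927259763368, 0.0307294689037843, 0.831584400419232, -0.3927259763368, -0.3927259763368, 0.0307294689037843, -0.831584400419232, -0.3927259763368, -0.3927259763368, 0.0307294689037843, 0.881813287779429, 0.471598691151316, 0, 0.0303784768311363, -0.881813287779429, 0.471598691151316, 0, 0.0303784768311363, 0.881813287779429, -0.471598691151316, 0, 0.0303784768311363, -0.881813287779429, -0.471598691151316, 0, 0.0303784768311363, 0.471598691151316, 0.881813287779429, 0, 0.0303784768311363, -0.471598691151316, 0.881813287779429, 0, 0.0303784768311363, 0.471598691151316, -0.881813287779429, 0, 0.0303784768311363, -0.471598691151316, -0.881813287779429, 0, 0.0303784768311363, 0.881813287779429, 0, 0.471598691151316, 0.0303784768311363, -0.881813287779429, 0, 0.471598691151316, 0.0303784768311363, 0.881813287779429, 0, -0.471598691151316, 0.0303784768311363, -0.881813287779429, 0, -0.471598691151316, 0.0303784768311363, 0.471598691151316, 0, 0.881813287779429, 0.0303784768311363, -0.471598691151316, 0, 0.881813287779429, 0.0303784768311363, 0.471598691151316, 0, -0.881813287779429, 0.0303784768311363, -0.471598691151316, 0, -0.881813287779429, 0.0303784768311363, 0, 0.881813287779429, 0.471598691151316, 0.0303784768311363, 0, -0.881813287779429, 0.471598691151316, 0.0303784768311363, 0, 0.881813287779429, -0.471598691151316, 0.0303784768311363, 0, -0.881813287779429, -0.471598691151316, 0.0303784768311363, 0, 0.471598691151316, 0.881813287779429, 0.0303784768311363, 0, -0.471598691151316, 0.881813287779429, 0.0303784768311363, 0, 0.471598691151316, -0.881813287779429, 0.0303784768311363, 0, -0.471598691151316, -0.881813287779429, 0.0303784768311363, 0.977642811118265, 0.210272522857307, 0, 0.0240137220378529, -0.977642811118265, 0.210272522857307, 0, 0.0240137220378529, 0.977642811118265, -0.210272522857307, 0, 0.0240137220378529, -0.977642811118265, -0.210272522857307, 0, 0.0240137220378529, 0.210272522857307, 0.977642811118265, 0, 0.0240137220378529, -0.210272522857307, 0.977642811118265, 0, 0.0240137220378529, 0.210272522857307, -0.977642811118265, 0, 0.0240137220378529, -0.210272522857307, -0.977642811118265, 0, 0.0240137220378529, 0.977642811118265, 0, 0.210272522857307, 0.0240137220378529, -0.977642811118265, 0, 0.210272522857307, 0.0240137220378529, 0.977642811118265, 0, -0.210272522857307, 0.0240137220378529, -0.977642811118265, 0, -0.210272522857307, 0.0240137220378529, 0.210272522857307, 0, 0.977642811118265, 0.0240137220378529, -0.210272522857307, 0, 0.977642811118265, 0.0240137220378529, 0.210272522857307, 0, -0.977642811118265, 0.0240137220378529, -0.210272522857307, 0, -0.977642811118265, 0.0240137220378529, 0, 0.977642811118265, 0.210272522857307, 0.0240137220378529, 0, -0.977642811118265, 0.210272522857307, 0.0240137220378529, 0, 0.977642811118265, -0.210272522857307, 0.0240137220378529, 0, -0.977642811118265, -0.210272522857307, 0.0240137220378529, 0, 0.210272522857307, 0.977642811118265, 0.0240137220378529, 0, -0.210272522857307, 0.977642811118265, 0.0240137220378529, 0, 0.210272522857307, -0.977642811118265, 0.0240137220378529, 0, -0.210272522857307, -0.977642811118265, 0.0240137220378529, 0.205482369640304, 0.868946032287241, 0.450233038258262, 0.0303720386859647, -0.205482369640304, 0.868946032287241, 0.450233038258262, 0.0303720386859647, 0.205482369640304, -0.868946032287241, 0.450233038258262, 0.0303720386859647, 0.205482369640304, 0.868946032287241, -0.450233038258262, 0.0303720386859647, -0.205482369640304, -0.868946032287241, 0.450233038258262, 0.0303720386859647, 0.205482369640304, -0.868946032287241, -0.450233038258262, 0.0303720386859647, -0.205482369640304, 0.868946032287241, -0.450233038258262, 0.0303720386859647, -0.205482369640304, -0.868946032287241, -0.450233038258262, 0.0303720386859647, 0.868946032287241, 0.205482369640304, 0.450233038258262, 0.0303720386859647, -0.868946032287241, 0.205482369640304, 0.450233038258262, 0.0303720386859647, 0.868946032287241, -0.205482369640304, 0.450233038258262, 0.0303720386859647, 0.868946032287241, 0.205482369640304, -0.450233038258262, 0.0303720386859647, -0.868946032287241, -0.205482369640304, 0.450233038258262, 0.0303720386859647, 0.868946032287241, -0.205482369640304, -0.450233038258262, 0.0303720386859647, -0.868946032287241, 0.205482369640304, -0.450233038258262, 0.0303720386859647, -0.868946032287241, -0.205482369640304, -0.450233038258262, 0.0303720386859647, 0.450233038258262, 0.205482369640304, 0.868946032287241, 0.0303720386859647, -0.450233038258262, 0.205482369640304, 0.868946032287241, 0.0303720386859647, 0.450233038258262, -0.205482369640304, 0.868946032287241, 0.0303720386859647, 0.450233038258262, 0.205482369640304, -0.868946032287241, 0.0303720386859647, -0.450233038258262, -0.205482369640304, 0.868946032287241, 0.0303720386859647, 0.450233038258262, -0.205482369640304, -0.868946032287241, 0.0303720386859647, -0.450233038258262, 0.205482369640304, -0.868946032287241, 0.0303720386859647, -0.450233038258262, -0.205482369640304, -0.868946032287241, 0.0303720386859647, 0.450233038258262, 0.868946032287241, 0.205482369640304, 0.0303720386859647, -0.450233038258262, 0.868946032287241, 0.205482369640304, 0.0303720386859647, 0.450233038258262, -0.868946032287241, 0.205482369640304, 0.0303720386859647, 0.450233038258262, 0.868946032287241, -0.205482369640304, 0.0303720386859647, -0.450233038258262, -0.868946032287241, 0.205482369640304, 0.0303720386859647, 0.450233038258262, -0.868946032287241, -0.205482369640304, 0.0303720386859647, -0.450233038258262, 0.868946032287241, -0.205482369640304, 0.0303720386859647, -0.450233038258262, -0.868946032287241, -0.205482369640304, 0.0303720386859647, 0.205482369640304, 0.450233038258262, 0.868946032287241, 0.0303720386859647, -0.205482369640304, 0.450233038258262, 0.868946032287241, 0.0303720386859647, 0.205482369640304, -0.450233038258262, 0.868946032287241, 0.0303720386859647, 0.205482369640304, 0.450233038258262, -0.868946032287241, 0.0303720386859647, -0.205482369640304, -0.450233038258262, 0.868946032287241, 0.0303720386859647, 0.205482369640304, -0.450233038258262, -0.868946032287241, 0.0303720386859647, -0.205482369640304, 0.450233038258262, -0.868946032287241, 0.0303720386859647, -0.205482369640304, -0.450233038258262, -0.868946032287241, 0.0303720386859647, 0.868946032287241, 0.450233038258262, 0.205482369640304, 0.0303720386859647, -0.868946032287241, 0.450233038258262, 0.205482369640304, 0.0303720386859647, 0.868946032287241, -0.450233038258262, 0.205482369640304, 0.0303720386859647, 0.868946032287241, 0.450233038258262, -0.205482369640304, 0.0303720386859647, -0.868946032287241, -0.450233038258262, 0.205482369640304, 0.0303720386859647, 0.868946032287241, -0.450233038258262, -0.205482369640304, 0.0303720386859647, -0.868946032287241, 0.450233038258262, -0.205482369640304, 0.0303720386859647, -0.868946032287241, -0.450233038258262, -0.205482369640304, 0.0303720386859647, 0.590515704892527, 0.799927854385729, 0.106801826075805, 0.0315696993854968, -0.590515704892527, 0.799927854385729, 0.106801826075805, 0.0315696993854968, 0.590515704892527, -0.799927854385729, 0.106801826075805, 0.0315696993854968, 0.590515704892527, 0.799927854385729, -0.106801826075805, 0.0315696993854968, -0.590515704892527, -0.799927854385729, 0.106801826075805, 0.0315696993854968, 0.590515704892527, -0.799927854385729, -0.106801826075805, 0.0315696993854968, -0.590515704892527, 0.799927854385729, -0.106801826075805, 0.0315696993854968, -0.590515704892527, -0.799927854385729, -0.106801826075805, 0.0315696993854968, 0.799927854385729, 0.590515704892527, 0.106801826075805, 0.0315696993854968, -0.799927854385729, 0.590515704892527, 0.106801826075805, 0.0315696993854968, 0.799927854385729, -0.590515704892527, 0.106801826075805, 0.0315696993854968, 0.799927854385729, 0.590515704892527, -0.106801826075805, 0.0315696993854968, -0.799927854385729, -0.590515704892527, 0.106801826075805, 0.0315696993854968, 0.799927854385729, -0.590515704892527, -0.106801826075805, 0.0315696993854968, -0.799927854385729, 0.590515704892527, -0.106801826075805, 0.0315696993854968, -0.799927854385729, -0.590515704892527, -0.106801826075805, 0.0315696993854968, 0.106801826075805, 0.590515704892527, 0.799927854385729, 0.0315696993854968, -0.106801826075805, 0.590515704892527, 0.799927854385729, 0.0315696993854968, 0.106801826075805, -0.590515704892527, 0.799927854385729, 0.0315696993854968, 0.106801826075805, 0.590515704892527, -0.799927854385729, 0.0315696993854968, -0.106801826075805, -0.590515704892527, 0.799927854385729, 0.0315696993854968, 0.106801826075805, -0.590515704892527, -0.799927854385729, 0.0315696993854968, -0.106801826075805, 0.590515704892527, -0.799927854385729, 0.0315696993854968, -0.106801826075805, -0.590515704892527, -0.799927854385729, 0.0315696993854968, 0.106801826075805, 0.799927854385729, 0.590515704892527, 0.0315696993854968, -0.106801826075805, 0.799927854385729, 0.590515704892527, 0.0315696993854968, 0.106801826075805, -0.799927854385729, 0.590515704892527, 0.0315696993854968, 0.106801826075805, 0.799927854385729, -0.590515704892527, 0.0315696993854968, -0.106801826075805, -0.799927854385729, 0.590515704892527, 0.0315696993854968, 0.106801826075805, -0.799927854385729, -0.590515704892527, 0.0315696993854968, -0.106801826075805, 0.799927854385729, -0.590515704892527, 0.0315696993854968, -0.106801826075805, -0.799927854385729, -0.590515704892527, 0.0315696993854968, 0.590515704892527, 0.106801826075805, 0.799927854385729, 0.0315696993854968, -0.590515704892527, 0.106801826075805, 0.799927854385729, 0.0315696993854968, 0.590515704892527, -0.106801826075805, 0.799927854385729, 0.0315696993854968, 0.590515704892527, 0.106801826075805, -0.799927854385729, 0.0315696993854968, -0.590515704892527, -0.106801826075805, 0.799927854385729, 0.0315696993854968, 0.590515704892527, -0.106801826075805, -0.799927854385729, 0.0315696993854968, -0.590515704892527, 0.106801826075805, -0.799927854385729, 0.0315696993854968, -0.590515704892527, -0.106801826075805, -0.799927854385729, 0.0315696993854968, 0.799927854385729, 0.106801826075805, 0.590515704892527, 0.0315696993854968, -0.799927854385729, 0.106801826075805, 0.590515704892527, 0.0315696993854968, 0.799927854385729, -0.106801826075805, 0.590515704892527, 0.0315696993854968, 0.799927854385729, 0.106801826075805, -0.590515704892527, 0.0315696993854968, -0.799927854385729, -0.106801826075805, 0.590515704892527, 0.0315696993854968, 0.799927854385729, -0.106801826075805, -0.590515704892527, 0.0315696993854968, -0.799927854385729, 0.106801826075805, -0.590515704892527, 0.0315696993854968, -0.799927854385729, -0.106801826075805, -0.590515704892527, 0.0315696993854968, 0.555015236107681, 0.77174626269159, 0.310428403516654, 0.0313737544816504, -0.555015236107681, 0.77174626269159, 0.310428403516654, 0.0313737544816504, 0.555015236107681, -0.77174626269159, 0.310428403516654, 0.0313737544816504, 0.555015236107681, 0.77174626269159, -0.310428403516654, 0.0313737544816504, -0.555015236107681, -0.77174626269159, 0.310428403516654, 0.0313737544816504, 0.555015236107681, -0.77174626269159, -0.310428403516654, 0.0313737544816504, -0.555015236107681, 0.77174626269159, -0.310428403516654, 0.0313737544816504, -0.555015236107681, -0.77174626269159, -0.310428403516654, 0.0313737544816504, 0.77174626269159, 0.555015236107681, 0.310428403516654, 0.0313737544816504, -0.77174626269159, 0.555015236107681, 0.310428403516654, 0.0313737544816504, 0.77174626269159, -0.555015236107681, 0.310428403516654, 0.0313737544816504, 0.77174626269159, 0.555015236107681, -0.310428403516654, 0.0313737544816504, -0.77174626269159, -0.555015236107681, 0.310428403516654, 0.0313737544816504, 0.77174626269159, -0.555015236107681, -0.310428403516654, 0.0313737544816504, -0.77174626269159, 0.555015236107681, -0.310428403516654, 0.0313737544816504, -0.77174626269159, -0.555015236107681, -0.310428403516654, 0.0313737544816504, 0.310428403516654, 0.555015236107681, 0.77174626269159, 0.0313737544816504, -0.310428403516654, 0.555015236107681, 0.77174626269159, 0.0313737544816504, 0.310428403516654, -0.555015236107681, 0.77174626269159, 0.0313737544816504, 0.310428403516654, 0.555015236107681, -0.77174626269159, 0.0313737544816504, -0.310428403516654, -0.555015236107681, 0.77174626269159, 0.0313737544816504, 0.310428403516654, -0.555015236107681, -0.77174626269159, 0.0313737544816504, -0.310428403516654, 0.555015236107681, -0.77174626269159, 0.0313737544816504, -0.310428403516654, -0.555015236107681, -0.77174626269159, 0.0313737544816504, 0.310428403516654, 0.77174626269159, 0.555015236107681, 0.0313737544816504, -0.310428403516654, 0.77174626269159, 0.555015236107681, 0.0313737544816504, 0.310428403516654, -0.77174626269159, 0.555015236107681, 0.0313737544816504, 0.310428403516654, 0.77174626269159, -0.555015236107681, 0.0313737544816504, -0.310428403516654, -0.77174626269159, 0.555015236107681, 0.0313737544816504, 0.310428403516654, -0.77174626269159, -0.555015236107681, 0.0313737544816504, -0.310428403516654, 0.77174626269159, -0.555015236107681, 0.0313737544816504, -0.310428403516654, -0.77174626269159, -0.555015236107681, 0.0313737544816504, 0.555015236107681, 0.310428403516654, 0.77174626269159, 0.0313737544816504, -0.555015236107681, 0.310428403516654, 0.77174626269159, 0.0313737544816504, 0.555015236107681, -0.310428403516654, 0.77174626269159, 0.0313737544816504, 0.555015236107681, 0.310428403516654, -0.77174626269159, 0.0313737544816504, -0.555015236107681, -0.310428403516654, 0.77174626269159, 0.0313737544816504, 0.555015236107681, -0.310428403516654, -0.77174626269159, 0.0313737544816504, -0.555015236107681, 0.310428403516654, -0.77174626269159, 0.0313737544816504, -0.555015236107681, -0.310428403516654, -0.77174626269159, 0.0313737544816504, 0.77174626269159, 0.310428403516654, 0.555015236107681, 0.0313737544816504, -0.77174626269159, 0.310428403516654, 0.555015236107681, 0.0313737544816504, 0.77174626269159, -0.310428403516654, 0.555015236107681, 0.0313737544816504, 0.77174626269159, 0.310428403516654, -0.555015236107681, 0.0313737544816504, -0.77174626269159, -0.310428403516654, 0.555015236107681, 0.0313737544816504, 0.77174626269159, -0.310428403516654, -0.555015236107681, 0.0313737544816504, -0.77174626269159, 0.310428403516654, -0.555015236107681, 0.0313737544816504, -0.77174626269159, -0.310428403516654, -0.555015236107681, 0.0313737544816504, 0.937180985855372, 0.334436314534346, 0.0992176963642925, 0.0281060420366139, -0.937180985855372, 0.334436314534346, 0.0992176963642925, 0.0281060420366139, 0.937180985855372, -0.334436314534346, 0.0992176963642925, 0.0281060420366139, 0.937180985855372, 0.334436314534346, -0.0992176963642925, 0.0281060420366139, -0.937180985855372, -0.334436314534346, 0.0992176963642925, 0.0281060420366139, 0.937180985855372, -0.334436314534346, -0.0992176963642925, 0.0281060420366139, -0.937180985855372, 0.334436314534346, -0.0992176963642925, 0.0281060420366139, -0.937180985855372, -0.334436314534346, -0.0992176963642925, 0.0281060420366139, 0.334436314534346, 0.937180985855372, 0.0992176963642925, 0.0281060420366139, -0.334436314534346, 0.937180985855372, 0.0992176963642925, 0.0281060420366139, 0.334436314534346, -0.937180985855372, 0.0992176963642925, 0.0281060420366139, 0.334436314534346, 0.937180985855372, -0.0992176963642925, 0.0281060420366139, -0.334436314534346, -0.937180985855372, 0.0992176963642925, 0.0281060420366139, 0.334436314534346, -0.937180985855372, -0.0992176963642925, 0.0281060420366139, -0.334436314534346, 0.937180985855372, -0.0992176963642925, 0.0281060420366139, -0.334436314534346, -0.937180985855372, -0.0992176963642925, 0.0281060420366139, 0.0992176963642925, 0.937180985855372, 0.334436314534346, 0.0281060420366139, -0.0992176963642925, 0.937180985855372, 0.334436314534346, 0.0281060420366139, 0.0992176963642925, -0.937180985855372, 0.334436314534346, 0.0281060420366139, 0.0992176963642925, 0.937180985855372, -0.334436314534346, 0.0281060420366139, -0.0992176963642925, -0.937180985855372, 0.334436314534346, 0.0281060420366139, 0.0992176963642925, -0.937180985855372, -0.334436314534346, 0.0281060420366139, -0.0992176963642925, 0.937180985855372, -0.334436314534346, 0.0281060420366139, -0.0992176963642925, -0.937180985855372, -0.334436314534346, 0.0281060420366139, 0.0992176963642925, 0.334436314534346, 0.937180985855372, 0.0281060420366139, -0.0992176963642925, 0.334436314534346, 0.937180985855372, 0.0281060420366139, 0.0992176963642925, -0.334436314534346, 0.937180985855372, 0.0281060420366139, 0.0992176963642925, 0.334436314534346, -0.937180985855372, 0.0281060420366139, -0.0992176963642925, -0.334436314534346, 0.937180985855372, 0.0281060420366139, 0.0992176963642925, -0.334436314534346, -0.937180985855372, 0.0281060420366139, -0.0992176963642925, 0.334436314534346, -0.937180985855372, 0.0281060420366139, -0.0992176963642925, -0.334436314534346, -0.937180985855372, 0.0281060420366139, 0.937180985855372, 0.0992176963642925, 0.334436314534346, 0.0281060420366139, -0.937180985855372, 0.0992176963642925, 0.334436314534346, 0.0281060420366139, 0.937180985855372, -0.0992176963642925, 0.334436314534346, 0.0281060420366139, 0.937180985855372, 0.0992176963642925, -0.334436314534346, 0.0281060420366139, -0.937180985855372, -0.0992176963642925, 0.334436314534346, 0.0281060420366139, 0.937180985855372, -0.0992176963642925, -0.334436314534346, 0.0281060420366139, -0.937180985855372, 0.0992176963642925, -0.334436314534346, 0.0281060420366139, -0.937180985855372, -0.0992176963642925, -0.334436314534346, 0.0281060420366139, 0.334436314534346, 0.0992176963642925, 0.937180985855372, 0.0281060420366139, -0.334436314534346, 0.0992176963642925, 0.937180985855372, 0.0281060420366139, 0.334436314534346, -0.0992176963642925, 0.937180985855372, 0.0281060420366139, 0.334436314534346, 0.0992176963642925, -0.937180985855372, 0.0281060420366139, -0.334436314534346, -0.0992176963642925, 0.937180985855372, 0.0281060420366139, 0.334436314534346, -0.0992176963642925, -0.937180985855372, 0.0281060420366139, -0.334436314534346, 0.0992176963642925, -0.937180985855372, 0.0281060420366139, -0.334436314534346, -0.0992176963642925, -0.937180985855372, 0.0281060420366139), ncol = 4L, byrow = TRUE)
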