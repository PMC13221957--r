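# lexnet pinned English stopword list, version 1.
# One lowercase token per line; lines starting with '#' are ignored.
a
an
the
and
but
or
nor
so
if
then
than
that
this
these
those
i
me
my
mine
myself
we
us
our
ours
ourselves
you
your
yours
yourself
yourselves
she
her
hers
herself
he
him
his
himself
they
them
their
theirs
themselves
it
its
itself
what
which
who
whom
whose
when
where
why
how
am
is
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
would
should
could
can
may
might
must
shall
of
to
in
on
at
by
for
with
from
into
onto
about
over
under
through
between
during
before
after
against
toward
towards
up
down
out
off
above
below
again
further
once
here
there
all
any
both
each
few
more
most
other
some
such
only
own
same
very
too
just
also
as
because
while
until
no
not
don't
didn't
doesn't
isn't
wasn't
aren't
weren't
can't
couldn't
won't
wouldn't
shouldn't
haven't
hasn't
hadn't
now
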